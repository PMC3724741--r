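#' Configuration for the striped lipid-domain field generator
#'
#' Defaults reproduce the ternary mixture the toolkit targets: 3480 DPPC,
#' 2304 DLiPC and 1536 cholesterol beads (5:3:2 ratio) in a 44 x 46 nm
#' plane, split evenly between two leaflets.
#'
#' @param n_dppc,n_dlipc,n_chol Bead counts per species (one bead per
#'   lipid molecule at this resolution).
#' @param stripe_fraction Fraction of the box width occupied by the DLiPC
#'   (liquid-disordered) stripe in the fully de-mixed state.
#' @param mixing_noise Positional jitter (nm), uniform in
#'   `[-mixing_noise, mixing_noise]`, applied to stripe placement.
#' @param box_xy Lateral box edges (nm).
#' @param box_z Box height (nm); leaflects sit at `box_z/2 - 1` and
#'   `box_z/2 + 1`.
#' @param seed RNG seed.
#' @return A `domain_field_config` list.
#' @export
domain_field_config <- function(n_dppc = 3480L, n_dlipc = 2304L,
                                n_chol = 1536L, stripe_fraction = 0.35,
                                mixing_noise = 0.1, box_xy = c(44, 46),
                                box_z = 14, seed = 1L) {
  if (any(c(n_dppc, n_dlipc, n_chol) < 0)) abort("bead counts must be >= 0")
  if (stripe_fraction < 0 || stripe_fraction > 1)
    abort("stripe_fraction must lie in [0, 1]")
  if (mixing_noise < 0) abort("mixing_noise must be >= 0")
  structure(list(n_dppc = as.integer(n_dppc), n_dlipc = as.integer(n_dlipc),
                 n_chol = as.integer(n_chol),
                 stripe_fraction = stripe_fraction,
                 mixing_noise = mixing_noise, box_xy = as.numeric(box_xy),
                 box_z = box_z, seed = as.integer(seed)),
            class = "domain_field_config")
}

#' Generate a (partially) de-mixed ternary lipid bead field
#'
#' At `demix_progress = 0` all species are uniformly mixed over the plane;
#' at 1, DLiPC occupies a stripe of width `stripe_fraction * box_x` and
#' DPPC/CHOL the remainder (modulo `mixing_noise` jitter). Intermediate
#' values assign each bead to its domain with probability
#' `demix_progress`, emulating progressive lipid de-mixing into
#' liquid-ordered and liquid-disordered stripes. Beads are split evenly
#' between the two leaflets (distinguished by z).
#'
#' @param config A [domain_field_config()].
#' @param demix_progress De-mixing fraction in `[0, 1]`.
#' @param time Frame time stamp (ns).
#' @return A list with `frame` (a `cg_frame`) and `topology`
#'   (`bead_topology`; lipid beads carry role `HEADGROUP`).
#' @export
generate_domain_field <- function(config, demix_progress = 1, time = 0) {
  stopifnot(inherits(config, "domain_field_config"))
  if (demix_progress < 0 || demix_progress > 1)
    abort("demix_progress must lie in [0, 1]")
  cfg <- config
  set.seed(cfg$seed)
  types <- rep(c("DLIPC", "DPPC", "CHOL"),
               c(cfg$n_dlipc, cfg$n_dppc, cfg$n_chol))
  n <- length(types)
  if (n == 0L) abort("domain field needs at least one bead")
  box <- c(cfg$box_xy, cfg$box_z)
  stripe_w <- cfg$stripe_fraction * box[1]

  in_domain <- runif(n) < demix_progress
  x <- numeric(n)
  ld <- types == "DLIPC"
  # domain placement: DLiPC inside the stripe, DPPC/CHOL outside
  sel <- in_domain & ld
  x[sel] <- runif(sum(sel), 0, stripe_w)
  sel <- in_domain & !ld
  x[sel] <- runif(sum(sel), stripe_w, box[1])
  sel <- !in_domain
  x[sel] <- runif(sum(sel), 0, box[1])
  if (cfg$mixing_noise > 0) {
    jit <- runif(n, -cfg$mixing_noise, cfg$mixing_noise)
    x <- (x + jit) %% box[1]
  }
  y <- runif(n, 0, box[2])
  leaflet <- rep_len(c(1L, 2L), n)
  z <- ifelse(leaflet == 1L, box[3] / 2 - 1, box[3] / 2 + 1)

  topo <- bead_topology(tibble::tibble(
    bead_id = seq_len(n) - 1L,
    molecule_id = seq_len(n),
    molecule_type = types,
    residue_index = 1L,
    bead_role = "HEADGROUP",
    bead_radius = 0.26))
  list(frame = cg_frame(time, box, cbind(x, y, z)), topology = topo)
}

#' Analytic solvent-accessible-surface-area fixtures
#'
#' Builds single-frame bead arrangements whose SASA is known in closed
#' form, for validating the Shrake-Rupley implementation:
#' `single_sphere` (area `4*pi*(r+probe)^2`), `two_spheres` at a given
#' center separation (spherical-cap overlap formula), and `buried_core`
#' (a bead fully enclosed by a shell of beads, area 0).
#'
#' @param kind One of `"single_sphere"`, `"two_spheres"`, `"buried_core"`.
#' @param r Bead radius (nm).
#' @param separation Center separation for `two_spheres` (nm, >= 0).
#' @param n_shell,shell_distance Shell bead count and center distance for
#'   `buried_core`.
#' @param box Box edges (nm); default is large so periodic images do not
#'   interfere.
#' @return A list with `frame`, `topology`, and `analytic_sasa` (total,
#'   nm^2, as a function of the probe radius).
#' @export
make_sasa_fixture <- function(kind = c("single_sphere", "two_spheres",
                                       "buried_core"),
                              r = 0.26, separation = NULL, n_shell = 60L,
                              shell_distance = 0.9, box = c(50, 50, 50)) {
  kind <- match.arg(kind)
  center <- box / 2
  if (kind == "single_sphere") {
    pos <- matrix(center, 1L, 3L)
    analytic <- function(probe) 4 * pi * (r + probe)^2
  } else if (kind == "two_spheres") {
    if (is.null(separation) || separation < 0)
      abort("two_spheres needs a non-negative separation")
    pos <- rbind(center - c(separation / 2, 0, 0),
                 center + c(separation / 2, 0, 0))
    analytic <- function(probe) {
      R <- r + probe
      if (separation >= 2 * R) return(2 * 4 * pi * R^2)
      h <- R - separation / 2          # buried cap height per sphere
      2 * (4 * pi * R^2 - 2 * pi * R * h)
    }
  } else {
    # Fibonacci shell around a core bead; dense enough to fully bury it
    k <- seq_len(n_shell)
    zu <- 1 - 2 * (k - 0.5) / n_shell
    ru <- sqrt(pmax(0, 1 - zu^2))
    phi <- k * pi * (3 - sqrt(5))
    shell <- cbind(ru * cos(phi), ru * sin(phi), zu) * shell_distance
    pos <- rbind(matrix(0, 1L, 3L), shell)
    pos <- sweep(pos, 2L, center, `+`)
    analytic <- function(probe) 0   # core bead only
  }
  n <- nrow(pos)
  topo <- bead_topology(tibble::tibble(
    bead_id = seq_len(n) - 1L, molecule_id = 1L, molecule_type = "PROTEIN",
    residue_index = seq_len(n), bead_role = "BACKBONE", bead_radius = r))
  list(frame = cg_frame(0, box, pos), topology = topo,
       analytic_sasa = analytic)
}
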
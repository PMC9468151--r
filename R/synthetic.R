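# Synthetic inputs with known ground truth: Ornstein-Uhlenbeck breathing
# ensembles written as pseudo-structures, the closed-form stationary
# exceedance oracle, planted-binder docking-score tables, and 4PL
# dose-response curves.
#
# All randomness flows from one integer seed.  Each logical stream (a
# pair, a compound class, a noise column) draws from its own derived RNG
# state, so adding streams never perturbs existing ones.

# independent, restorable RNG stream; returns a closure rng(n) -> n
# standard-normal draws.  Global .Random.seed is left untouched.
.stream_rng <- function(seed, stream) {
  derived <- (as.numeric(seed) * 100003 + as.numeric(stream) * 7919) %%
    2147483629
  env <- new.env()
  local({
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(derived), kind = "Mersenne-Twister")
    env$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  function(n) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- stats::rnorm(n)
    env$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    out
  }
}

#' Parameters of the synthetic pocket-breathing generator
#'
#' Defines four independent pseudo residue pairs whose distances follow a
#' stationary Ornstein-Uhlenbeck (OU) process, emulating the breathing of
#' a binding site over a trajectory.  The free variant fluctuates with SD
#' `sigma`; the tethered variant has its fluctuation damped by
#' `tether_factor` and its mean shifted down by `d0_shift` per pair,
#' emulating the rigidifying effect of membrane tethering.
#'
#' Defaults are chosen so the free form's SDRP (sum of the four pair
#' distances) concentrates in the 76-78 Angstrom bin and the tethered
#' form's in 70-72: `d0 = 19.3` per pair (sum 77.2) and
#' `d0_shift = 1.5` (tethered sum 71.2).
#'
#' @param d0 per-pair mean distance in Angstrom (length 1 or 4).
#' @param sigma stationary SD of the distance fluctuation in Angstrom.
#' @param tau correlation time in frames (>= 1); successive saved frames
#'   decorrelate after about `tau` steps.
#' @param tether_factor multiplier in `[0, 1]` on `sigma` for the
#'   tethered variant.
#' @param d0_shift per-pair mean reduction (Angstrom) in the tethered
#'   variant.
#' @param n_frames number of frames (>= 2).
#' @param seed integer master seed.
#' @return An object of class `"BreathingParams"`.
#' @export
breathing_params <- function(d0 = 19.3, sigma = 1.2, tau = 5,
                             tether_factor = 0.4, d0_shift = 1.5,
                             n_frames = 5000, seed = 1) {
  d0 <- rep_len(as.numeric(d0), 4L)
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau < 1) stop("tau must be >= 1")
  if (tether_factor < 0 || tether_factor > 1) {
    stop("tether_factor must lie in [0, 1]")
  }
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (any(d0 - d0_shift <= 0)) stop("d0_shift leaves a non-positive mean")
  structure(
    list(d0 = d0, sigma = sigma, tau = tau, tether_factor = tether_factor,
         d0_shift = d0_shift, n_frames = as.integer(n_frames),
         seed = as.integer(seed)),
    class = "BreathingParams"
  )
}

#' Default monitored pairs of the synthetic generator
#'
#' The generator plants four disjoint pseudo residue pairs (chain A
#' residues 101-104 against chain B residues 201-204).  Real monitored
#' pairs can share residues; the generator's pairs are disjoint so each
#' can follow an independent breathing process.
#'
#' @param distance_mode passed to [residue_pair()].
#' @return List of four [residue_pair()] objects labelled
#'   `"pair1"`..`"pair4"`.
#' @export
synthetic_pairs <- function(distance_mode = "sidechain_centroid") {
  lapply(1:4, function(i) {
    residue_pair("A", 100L + i, "B", 200L + i,
                 label = paste0("pair", i), distance_mode = distance_mode)
  })
}

# OU recursion started at the mean (the "crystal" reference conformation)
.ou_series <- function(n, d0, sigma_eff, tau, rng) {
  phi <- exp(-1 / tau)
  d <- numeric(n)
  d[1] <- d0
  if (sigma_eff == 0) {
    d[] <- d0
    return(d)
  }
  eps <- rng(n - 1L)
  innov_sd <- sqrt(1 - phi^2) * sigma_eff
  for (t in 2:n) {
    d[t] <- d0 + phi * (d[t - 1L] - d0) + innov_sd * eps[t - 1L]
  }
  d
}

#' Simulate a breathing ensemble with known ground truth
#'
#' Generates a multi-frame pseudo-structure in which each of four
#' monitored pair distances follows a discrete OU process
#' `d(t+1) = d0 + phi (d(t) - d0) + sqrt(1 - phi^2) sigma_eff eps`,
#' `phi = exp(-1/tau)`, started at `d0` (so frame 1 is the reference
#' conformation).  For the `"tethered"` variant
#' `sigma_eff = sigma * tether_factor` and the mean is lowered by
#' `d0_shift`.
#'
#' Each pair occupies its own axis: member A sits at a fixed origin and
#' member B at distance `d(t)` along x.  Pseudo-residues carry three heavy
#' atoms (N, CA, CB, offset along z) so all three distance modes resolve,
#' and all three reproduce the planted distance exactly.  Two static
#' scaffold residues on chain S exercise chain filtering.
#'
#' @param params a [breathing_params()] object.
#' @param variant `"free"` or `"tethered"`.
#' @return A list with `ensemble` (an [ensemble()]), `truth` (data.frame
#'   `frame`, `pair`, `distance` of planted distances), `pairs`
#'   (the [synthetic_pairs()]), and `params_effective` (per-pair `d0` and
#'   `sigma_eff` actually used).
#' @export
simulate_breathing_ensemble <- function(params,
                                        variant = c("free", "tethered")) {
  stopifnot(inherits(params, "BreathingParams"))
  variant <- match.arg(variant)
  tethered <- variant == "tethered"
  sigma_eff <- if (tethered) params$sigma * params$tether_factor else
    params$sigma
  d0 <- if (tethered) params$d0 - params$d0_shift else params$d0
  nf <- params$n_frames

  # one RNG stream per pair; tethered streams are distinct from free ones
  voffs <- if (tethered) 100L else 0L
  dists <- vapply(1:4, function(i) {
    .ou_series(nf, d0[i], sigma_eff, params$tau,
               .stream_rng(params$seed, voffs + i))
  }, numeric(nf))

  # atom table: 4 pair-member residues per chain A/B + 2 scaffold residues
  atom_z <- c(N = 0.8, CA = 0, CB = -0.8)
  res_atoms <- function(chain, resnum, resname) {
    data.frame(chain = chain, resnum = resnum, resname = resname,
               atom_name = names(atom_z), element = c("N", "C", "C"),
               stringsAsFactors = FALSE)
  }
  resnames <- c("TYR", "GLN", "LYS", "HIS")
  atoms <- do.call(rbind, c(
    lapply(1:4, function(i) res_atoms("A", 100L + i, resnames[i])),
    lapply(1:4, function(i) res_atoms("B", 200L + i, "ASP")),
    list(res_atoms("S", 1L, "GLY"), res_atoms("S", 2L, "ALA"))
  ))
  n_atoms <- nrow(atoms)

  coords <- array(0, dim = c(n_atoms, 3L, nf))
  for (i in 1:4) {
    a_rows <- which(atoms$chain == "A" & atoms$resnum == 100L + i)
    b_rows <- which(atoms$chain == "B" & atoms$resnum == 200L + i)
    y <- 50 * i
    coords[a_rows, 1, ] <- 0
    coords[a_rows, 2, ] <- y
    coords[a_rows, 3, ] <- atom_z[atoms$atom_name[a_rows]]
    coords[b_rows, 1, ] <- rep(dists[, i], each = length(b_rows))
    coords[b_rows, 2, ] <- y
    coords[b_rows, 3, ] <- atom_z[atoms$atom_name[b_rows]]
  }
  for (s in 1:2) {
    s_rows <- which(atoms$chain == "S" & atoms$resnum == s)
    coords[s_rows, 1, ] <- -20 - 5 * s
    coords[s_rows, 2, ] <- -10
    coords[s_rows, 3, ] <- atom_z[atoms$atom_name[s_rows]]
  }

  truth <- data.frame(
    frame = rep(seq_len(nf), times = 4L),
    pair = rep(paste0("pair", 1:4), each = nf),
    distance = as.vector(dists),
    stringsAsFactors = FALSE
  )
  list(
    ensemble = ensemble(atoms, coords, source_path = "synthetic"),
    truth = truth,
    pairs = synthetic_pairs(),
    params_effective = list(d0 = d0, sigma_eff = sigma_eff,
                            variant = variant)
  )
}

#' Closed-form stationary exceedance probability
#'
#' Under the stationary OU law the distance deviation from its mean is
#' Gaussian with SD `sigma`, so the one-sided exceedance probability is
#' `P(d - d0 > t) = 1 - pnorm(t / sigma)`.  This is the independent
#' oracle against which measured exceedance on simulated ensembles is
#' checked.
#'
#' @param sigma stationary SD in Angstrom (> 0).
#' @param threshold deviation threshold in Angstrom (> 0).
#' @return Probability in `(0, 0.5)`.
#' @export
analytic_exceedance <- function(sigma, threshold) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (threshold <= 0) stop("threshold must be > 0")
  1 - stats::pnorm(threshold / sigma)
}

#' Specification of a planted virtual screen
#'
#' @param n_compounds library size.
#' @param n_selective compounds planted to pass every cascade rule
#'   (selective for the primary target).
#' @param n_pan compounds planted to bind both targets (removed by the
#'   differential rule).
#' @param seed integer master seed.
#' @return An object of class `"PlantedScreen"`.
#' @export
planted_screen <- function(n_compounds = 500, n_selective = 20,
                           n_pan = 50, seed = 1) {
  if (n_selective + n_pan > n_compounds) {
    stop("n_selective + n_pan must not exceed n_compounds")
  }
  structure(
    list(n_compounds = as.integer(n_compounds),
         n_selective = as.integer(n_selective),
         n_pan = as.integer(n_pan), seed = as.integer(seed)),
    class = "PlantedScreen"
  )
}

#' Simulate docking-score tables with planted selective binders
#'
#' Builds a long-format score table for two targets (`sRANKL`, `mRANKL`)
#' and three scorers: `moe` (primary, used by the differential rule with
#' cutoff -6), `glide` (secondary, threshold rule at -3.5) and `ifd`
#' (induced-fit re-ranking).  Planted selective compounds satisfy
#' `score(moe, sRANKL) < -6` and `score(moe, mRANKL) >= -6` and
#' `score(glide, sRANKL) < -3.5`, each with margin >= 0.5 score units;
#' pan binders clear both moe cutoffs (and so fail the differential
#' rule); decoys fail at least one rule with margin.
#'
#' @param spec a [planted_screen()] specification.
#' @return A list with `table` (a [score_table()]) and `labels`
#'   (data.frame `compound_id`, `class` in selective/pan/decoy).
#' @export
simulate_score_tables <- function(spec = planted_screen()) {
  stopifnot(inherits(spec, "PlantedScreen"))
  n <- spec$n_compounds
  ids <- sprintf("cmpd%04d", seq_len(n))
  cls <- rep("decoy", n)
  cls[seq_len(spec$n_selective)] <- "selective"
  if (spec$n_pan > 0) {
    cls[spec$n_selective + seq_len(spec$n_pan)] <- "pan"
  }

  rng <- list(moe_s = .stream_rng(spec$seed, 11L),
              moe_m = .stream_rng(spec$seed, 12L),
              glide = .stream_rng(spec$seed, 13L),
              ifd   = .stream_rng(spec$seed, 14L))
  half_norm <- function(draws) abs(draws)   # margin-respecting offsets

  moe_s <- moe_m <- glide_s <- ifd_s <- numeric(n)
  sel <- cls == "selective"; pan <- cls == "pan"; dec <- cls == "decoy"
  # selective: strong on sRANKL, weak on mRANKL, pass glide, strong ifd
  moe_s[sel]   <- -6.5 - half_norm(rng$moe_s(sum(sel)))
  moe_m[sel]   <- -5.5 + half_norm(rng$moe_m(sum(sel)))
  glide_s[sel] <- -4.0 - half_norm(rng$glide(sum(sel)))
  ifd_s[sel]   <- -7.0 - half_norm(rng$ifd(sum(sel)))
  # pan binders: strong on both forms -> removed by the differential rule
  moe_s[pan]   <- -6.5 - half_norm(rng$moe_s(sum(pan)))
  moe_m[pan]   <- -6.5 - half_norm(rng$moe_m(sum(pan)))
  glide_s[pan] <- -4.0 - half_norm(rng$glide(sum(pan)))
  ifd_s[pan]   <- -5.0 + rng$ifd(sum(pan))
  # decoys: weak primary docking -> fail the differential positive rule
  moe_s[dec]   <- -5.5 + half_norm(rng$moe_s(sum(dec)))
  moe_m[dec]   <- -4.0 + rng$moe_m(sum(dec))
  glide_s[dec] <- -3.0 + half_norm(rng$glide(sum(dec)))
  ifd_s[dec]   <- -3.0 + rng$ifd(sum(dec))

  tab <- rbind(
    data.frame(compound_id = ids, target_id = "sRANKL", scorer_id = "moe",
               score = round(moe_s, 3), stringsAsFactors = FALSE),
    data.frame(compound_id = ids, target_id = "mRANKL", scorer_id = "moe",
               score = round(moe_m, 3), stringsAsFactors = FALSE),
    data.frame(compound_id = ids, target_id = "sRANKL", scorer_id = "glide",
               score = round(glide_s, 3), stringsAsFactors = FALSE),
    data.frame(compound_id = ids, target_id = "sRANKL", scorer_id = "ifd",
               score = round(ifd_s, 3), stringsAsFactors = FALSE)
  )
  list(table = score_table(tab, provenance = "synthetic"),
       labels = data.frame(compound_id = ids, class = cls,
                           stringsAsFactors = FALSE))
}

#' Default cascade configuration for the two-step funnel
#'
#' Stage 1 keeps differential binders (primary-scorer score below -6 on
#' the soluble form only), stage 2 applies the secondary-scorer threshold
#' of -3.5, and an optional final stage keeps the `k` best induced-fit
#' scores.
#'
#' @param k_final number of induced-fit survivors to retain; `NULL` skips
#'   the re-ranking stage.
#' @return A [cascade_config()].
#' @export
default_cascade_config <- function(k_final = NULL) {
  stages <- list(
    stage_differential_binder("moe", "sRANKL", "mRANKL", -6),
    stage_threshold("glide", "sRANKL", -3.5)
  )
  if (!is.null(k_final)) {
    stages <- c(stages, list(stage_rank_top("ifd", "sRANKL", k_final)))
  }
  do.call(cascade_config, stages)
}

#' Simulate a dose-response curve from a 4PL model
#'
#' @param bottom,top,ic50,hill generating 4PL parameters (`ic50 > 0`).
#' @param doses positive, strictly increasing concentrations; default nine
#'   half-log-spaced doses bracketing `ic50`.
#' @param noise_sd SD of additive Gaussian noise on the response scale.
#' @param seed integer seed.
#' @return A data.frame with columns `dose` and `response`, plus
#'   attribute `truth` holding the generating parameters.
#' @export
simulate_dose_response <- function(bottom = 0, top = 100, ic50 = 1,
                                   hill = 1, doses = NULL, noise_sd = 0,
                                   seed = 1) {
  if (ic50 <= 0) stop("ic50 must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(doses)) {
    doses <- ic50 * 10^seq(-2, 2, length.out = 9)
  }
  if (any(doses <= 0) || any(diff(doses) <= 0)) {
    stop("doses must be positive and strictly increasing")
  }
  resp <- .logistic4_eval(doses, bottom, top, ic50, hill)
  if (noise_sd > 0) {
    resp <- resp + noise_sd * .stream_rng(seed, 31L)(length(doses))
  }
  out <- data.frame(dose = doses, response = resp)
  attr(out, "truth") <- c(bottom = bottom, top = top, ic50 = ic50,
                          hill = hill)
  out
}
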
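# Residue-pair distance analysis of conformational ensembles: per-frame
# distance series, exceedance probabilities relative to a reference
# conformation, the SDRP pocket-breathing statistic with modal-bin
# representative selection, and two-ensemble comparison.

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Define a monitored residue pair
#'
#' A residue pair names two residues (by chain and residue number) whose
#' inter-residue distance is tracked across an ensemble.  The distance mode
#' controls which atoms define the residue position:
#' `"sidechain_centroid"` (default) uses the centroid of side-chain heavy
#' atoms (the C-alpha for glycine), `"ca"` the C-alpha atom, and
#' `"min_heavy"` the minimum over all heavy-atom pairs.  Hydrogens are
#' ignored in every mode.
#'
#' @param chain_a,resnum_a,chain_b,resnum_b chain identifier and residue
#'   number of the two members; the members must be distinct.
#' @param label short display label, e.g. `"Y234-H224"`.
#' @param distance_mode one of `"sidechain_centroid"`, `"ca"`,
#'   `"min_heavy"`.
#' @return An object of class `"ResiduePair"`.
#' @export
residue_pair <- function(chain_a, resnum_a, chain_b, resnum_b,
                         label = NULL,
                         distance_mode = c("sidechain_centroid", "ca",
                                           "min_heavy")) {
  distance_mode <- match.arg(distance_mode)
  resnum_a <- as.integer(resnum_a); resnum_b <- as.integer(resnum_b)
  if (resnum_a < 1L || resnum_b < 1L) stop("residue numbers must be >= 1")
  if (identical(chain_a, chain_b) && resnum_a == resnum_b) {
    stop("the two members of a residue pair must be distinct")
  }
  if (is.null(label)) {
    label <- paste0(chain_a, resnum_a, "-", chain_b, resnum_b)
  }
  structure(
    list(chain_a = chain_a, resnum_a = resnum_a,
         chain_b = chain_b, resnum_b = resnum_b,
         label = label, distance_mode = distance_mode),
    class = "ResiduePair"
  )
}

#' @export
print.ResiduePair <- function(x, ...) {
  cat("ResiduePair ", x$label, " [", x$chain_a, x$resnum_a, " - ",
      x$chain_b, x$resnum_b, "], mode ", x$distance_mode, "\n", sep = "")
  invisible(x)
}

# rows of the atom table that represent one member under a distance mode
.select_member <- function(ens, chain, resnum, mode) {
  at <- ens$atoms
  in_res <- at$chain == chain & at$resnum == resnum
  heavy <- in_res & at$element != "H"
  idx <- switch(mode,
    ca = which(heavy & at$atom_name == "CA"),
    min_heavy = which(heavy),
    sidechain_centroid = {
      sc <- which(heavy & !(at$atom_name %in% .backbone_atoms))
      if (length(sc) == 0L) sc <- which(heavy & at$atom_name == "CA")
      sc
    }
  )
  if (length(idx) == 0L) {
    stop("selection error: no atoms for chain ", chain, " residue ", resnum,
         " under mode '", mode, "'")
  }
  idx
}

# n_frames vector of distances between two atom selections
.member_distance <- function(ens, idx_a, idx_b, mode) {
  if (mode == "min_heavy") {
    nf <- ens$frame_count
    dmin <- rep(Inf, nf)
    for (i in idx_a) {
      for (j in idx_b) {
        d2 <- (ens$coords[i, 1, ] - ens$coords[j, 1, ])^2 +
              (ens$coords[i, 2, ] - ens$coords[j, 2, ])^2 +
              (ens$coords[i, 3, ] - ens$coords[j, 3, ])^2
        dmin <- pmin(dmin, d2)
      }
    }
    sqrt(dmin)
  } else {
    centroid <- function(idx) {
      if (length(idx) == 1L) {
        matrix(ens$coords[idx, , ], nrow = 3L)
      } else {
        apply(ens$coords[idx, , , drop = FALSE], c(2, 3), mean)
      }
    }
    ca <- centroid(idx_a); cb <- centroid(idx_b)
    sqrt(colSums((ca - cb)^2))
  }
}

#' Per-frame distance series for a residue pair
#'
#' Computes the inter-residue distance at every frame of an ensemble under
#' the pair's distance mode, together with the distance in a designated
#' reference conformation (by default frame 1, the starting structure).
#'
#' @param ens an [ensemble()].
#' @param pair a [residue_pair()].
#' @param reference_frame 1-based frame index used as the reference
#'   conformation, or `"mean"` to use the trajectory mean distance.
#' @return An object of class `"DistanceSeries"`: a list with `pair`,
#'   `values` (Angstrom, length `frame_count`) and `reference_distance`.
#' @export
pair_distance_series <- function(ens, pair, reference_frame = 1L) {
  stopifnot(inherits(ens, "Ensemble"), inherits(pair, "ResiduePair"))
  idx_a <- .select_member(ens, pair$chain_a, pair$resnum_a, pair$distance_mode)
  idx_b <- .select_member(ens, pair$chain_b, pair$resnum_b, pair$distance_mode)
  values <- .member_distance(ens, idx_a, idx_b, pair$distance_mode)
  if (any(values == 0)) {
    stop("degenerate pair ", pair$label,
         ": members coincide in frame ", which(values == 0)[1])
  }
  if (identical(reference_frame, "mean")) {
    ref <- mean(values)
  } else {
    reference_frame <- as.integer(reference_frame)
    if (reference_frame < 1L || reference_frame > ens$frame_count) {
      stop("reference frame ", reference_frame, " out of range")
    }
    ref <- values[reference_frame]
  }
  structure(
    list(pair = pair, values = values, reference_distance = ref),
    class = "DistanceSeries"
  )
}

#' @export
print.DistanceSeries <- function(x, ...) {
  cat("DistanceSeries ", x$pair$label, ": ", length(x$values),
      " frames, mean ", sprintf("%.2f", mean(x$values)),
      " A (reference ", sprintf("%.2f", x$reference_distance), " A)\n",
      sep = "")
  invisible(x)
}

#' Exceedance probability of a distance series
#'
#' Fraction of frames in which the pair distance exceeds its reference
#' distance by strictly more than `threshold` Angstrom (a one-sided,
#' opening-direction criterion).
#'
#' @param series a [pair_distance_series()] result.
#' @param threshold positive deviation threshold in Angstrom (the
#'   flexibility analysis uses 1.8 or 2.0 A).
#' @return Probability in `[0, 1]`.
#' @export
exceedance_probability <- function(series, threshold = 1.8) {
  stopifnot(inherits(series, "DistanceSeries"))
  if (length(series$values) == 0L) stop("empty distance series")
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  mean(series$values - series$reference_distance > threshold)
}

#' SDRP profile of an ensemble
#'
#' The SDRP (sum of the distances of four monitored residue pairs) is
#' computed per frame and histogrammed into bins of width `bin_width`
#' anchored at integer multiples of the width, so that e.g. 76-78 A is a
#' bin label exactly.  The modal bin is the most populated one (ties broken
#' toward the lower edge), and its member frames, ranked by closeness of
#' their SDRP to the bin midpoint (ties by lower frame index), serve as
#' representative conformations for docking.
#'
#' @param ens an [ensemble()].
#' @param pairs list of exactly four [residue_pair()] objects.
#' @param bin_width histogram bin width in Angstrom (default 2).
#' @param reference_frame passed to [pair_distance_series()].
#' @return An object of class `"SDRPProfile"`: `sdrp_values` (Angstrom per
#'   frame), `per_pair` (matrix frame x pair), `breaks`, `counts`,
#'   `modal_bin` (`c(lo, hi)`), `representative_frames` (1-based indices).
#' @export
sdrp_profile <- function(ens, pairs, bin_width = 2, reference_frame = 1L) {
  if (!is.list(pairs) || length(pairs) != 4L ||
      !all(vapply(pairs, inherits, TRUE, "ResiduePair"))) {
    stop("'pairs' must be a list of exactly 4 ResiduePair objects")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  series <- lapply(pairs, function(p)
    pair_distance_series(ens, p, reference_frame))
  per_pair <- vapply(series, `[[`, numeric(ens$frame_count), "values")
  per_pair <- matrix(per_pair, nrow = ens$frame_count)
  colnames(per_pair) <- vapply(pairs, `[[`, "", "label")
  sdrp <- rowSums(per_pair)

  lo_idx <- floor(min(sdrp) / bin_width)
  hi_idx <- floor(max(sdrp) / bin_width)
  breaks <- (lo_idx:(hi_idx + 1L)) * bin_width
  bin_of <- floor(sdrp / bin_width) - lo_idx + 1L
  counts <- tabulate(bin_of, nbins = length(breaks) - 1L)
  modal_i <- which.max(counts)          # ties: lower edge wins
  modal_bin <- c(breaks[modal_i], breaks[modal_i + 1L])

  in_modal <- which(bin_of == modal_i)
  mid <- mean(modal_bin)
  ord <- order(abs(sdrp[in_modal] - mid), in_modal)
  reps <- in_modal[ord]

  structure(
    list(pairs = pairs, sdrp_values = sdrp, per_pair = per_pair,
         bin_width = bin_width, breaks = breaks, counts = counts,
         modal_bin = modal_bin, representative_frames = reps),
    class = "SDRPProfile"
  )
}

#' @export
print.SDRPProfile <- function(x, ...) {
  cat("SDRPProfile: ", length(x$sdrp_values), " frames, SDRP range ",
      sprintf("%.1f-%.1f", min(x$sdrp_values), max(x$sdrp_values)),
      " A\n  modal bin [", x$modal_bin[1], ", ", x$modal_bin[2],
      ") A with ", max(x$counts), " frames; representative frame ",
      x$representative_frames[1], "\n", sep = "")
  invisible(x)
}

#' Pocket length and width at one frame
#'
#' The binding-site size is summarised by two residue-pair distances
#' (length and width) measured on a single conformation, typically a
#' representative frame from the modal SDRP bin.
#'
#' @param ens an [ensemble()].
#' @param frame_index 1-based frame index.
#' @param length_pair,width_pair [residue_pair()] objects defining the two
#'   site dimensions.
#' @return An object of class `"PocketGeometry"` with `length`, `width`
#'   (Angstrom) and `frame_index`.
#' @export
pocket_geometry <- function(ens, frame_index, length_pair, width_pair) {
  stopifnot(inherits(ens, "Ensemble"))
  frame_index <- as.integer(frame_index)
  if (frame_index < 1L || frame_index > ens$frame_count) {
    stop("frame index ", frame_index, " out of range (1..",
         ens$frame_count, ")")
  }
  one <- function(pair) {
    s <- pair_distance_series(ens, pair, reference_frame = frame_index)
    s$values[frame_index]
  }
  structure(
    list(length_pair = length_pair, width_pair = width_pair,
         length = one(length_pair), width = one(width_pair),
         frame_index = frame_index),
    class = "PocketGeometry"
  )
}

#' @export
print.PocketGeometry <- function(x, ...) {
  cat(sprintf("PocketGeometry (frame %d): length %.2f A (%s), width %.2f A (%s)\n",
              x$frame_index, x$length, x$length_pair$label,
              x$width, x$width_pair$label))
  invisible(x)
}

#' Compare the flexibility of two ensembles
#'
#' Contrasts two conformational ensembles of the same protein (e.g. a free
#' and a membrane-tethered form) over four monitored residue pairs:
#' per-pair exceedance probabilities and their difference, modal SDRP bins,
#' pocket geometry at each ensemble's top representative frame, and a
#' per-pair / overall verdict on which ensemble is more flexible.
#'
#' @param ens_a,ens_b [ensemble()] objects (A is conventionally the free
#'   form).
#' @param pairs list of exactly four [residue_pair()] objects resolvable in
#'   both ensembles.
#' @param threshold exceedance threshold in Angstrom.
#' @param bin_width SDRP histogram bin width in Angstrom.
#' @param length_pair,width_pair optional pairs for pocket sizing at the
#'   representatives; default the first and third monitored pair.
#' @param reference_frame passed through to the distance series.
#' @return An object of class `"FlexComparison"`; deltas are exceedance(A)
#'   minus exceedance(B), and the per-pair verdict is `"A"`, `"B"` or
#'   `"tie"` by the sign of the delta.
#' @export
compare_ensembles <- function(ens_a, ens_b, pairs, threshold = 1.8,
                              bin_width = 2, length_pair = NULL,
                              width_pair = NULL, reference_frame = 1L) {
  if (is.null(length_pair)) length_pair <- pairs[[1]]
  if (is.null(width_pair)) width_pair <- pairs[[3]]
  exc <- function(ens) vapply(pairs, function(p)
    exceedance_probability(pair_distance_series(ens, p, reference_frame),
                           threshold), 0)
  exc_a <- exc(ens_a); exc_b <- exc(ens_b)
  delta <- exc_a - exc_b
  verdict <- ifelse(delta > 0, "A", ifelse(delta < 0, "B", "tie"))
  prof_a <- sdrp_profile(ens_a, pairs, bin_width, reference_frame)
  prof_b <- sdrp_profile(ens_b, pairs, bin_width, reference_frame)
  rep_a <- prof_a$representative_frames[1]
  rep_b <- prof_b$representative_frames[1]
  overall <- if (all(delta > 0)) "A" else if (all(delta < 0)) "B" else "mixed"
  structure(
    list(
      pair_labels = vapply(pairs, `[[`, "", "label"),
      exceedance_a = exc_a, exceedance_b = exc_b, delta = delta,
      verdict = verdict, overall_verdict = overall,
      threshold = threshold, bin_width = bin_width,
      modal_bin_a = prof_a$modal_bin, modal_bin_b = prof_b$modal_bin,
      profile_a = prof_a, profile_b = prof_b,
      representative_a = rep_a, representative_b = rep_b,
      pocket_a = pocket_geometry(ens_a, rep_a, length_pair, width_pair),
      pocket_b = pocket_geometry(ens_b, rep_b, length_pair, width_pair)
    ),
    class = "FlexComparison"
  )
}

#' @export
print.FlexComparison <- function(x, ...) {
  cat("Flexibility comparison (threshold ", x$threshold, " A):\n", sep = "")
  df <- data.frame(pair = x$pair_labels,
                   exceedance_A = round(x$exceedance_a, 4),
                   exceedance_B = round(x$exceedance_b, 4),
                   delta = round(x$delta, 4),
                   more_flexible = x$verdict)
  print(df, row.names = FALSE)
  cat(sprintf("modal SDRP bin: A [%g, %g) A, B [%g, %g) A\n",
              x$modal_bin_a[1], x$modal_bin_a[2],
              x$modal_bin_b[1], x$modal_bin_b[2]))
  cat(sprintf("pocket at representatives: A %.2f x %.2f A, B %.2f x %.2f A\n",
              x$pocket_a$length, x$pocket_a$width,
              x$pocket_b$length, x$pocket_b$width))
  cat("overall more flexible:", x$overall_verdict, "\n")
  invisible(x)
}
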
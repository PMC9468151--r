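# In-code fixtures: tiny hand-built ensembles with known geometry.

# ensemble of single-atom residues: `positions` is a list of frames, each
# a list of xyz vectors, one per residue; residue i sits on chain
# `chains[i]` with number `resnums[i]` and a single atom `atom`.
point_ensemble <- function(positions, chains, resnums, atom = "CB",
                           resname = "ALA") {
  n_res <- length(chains)
  atoms <- data.frame(chain = chains, resnum = resnums,
                      resname = resname, atom_name = atom,
                      element = substr(atom, 1, 1),
                      stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(n_res, 3, length(positions)))
  for (f in seq_along(positions)) {
    coords[, , f] <- do.call(rbind, positions[[f]])
  }
  ensemble(atoms, coords)
}

# two single-atom residues separated by the given distance per frame
dist_ensemble <- function(dists, atom = "CB") {
  frames <- lapply(dists, function(d) {
    list(c(0, 0, 0), c(d, 0, 0))
  })
  point_ensemble(frames, chains = c("A", "B"), resnums = c(1L, 2L),
                 atom = atom)
}

pair_ab <- function(mode = "sidechain_centroid") {
  residue_pair("A", 1, "B", 2, distance_mode = mode)
}

# four disjoint single-atom pairs with per-frame planted distances;
# `dist_mat` is frames x 4
four_pair_ensemble <- function(dist_mat) {
  n_f <- nrow(dist_mat)
  frames <- lapply(seq_len(n_f), function(f) {
    pos <- list()
    for (i in 1:4) {
      pos[[2 * i - 1]] <- c(0, 50 * i, 0)
      pos[[2 * i]] <- c(dist_mat[f, i], 50 * i, 0)
    }
    pos
  })
  point_ensemble(frames,
                 chains = rep(c("A", "B"), 4),
                 resnums = as.integer(c(1, 1, 2, 2, 3, 3, 4, 4)))
}

four_pairs <- function(mode = "sidechain_centroid") {
  lapply(1:4, function(i) {
    residue_pair("A", i, "B", i, label = paste0("hp", i),
                 distance_mode = mode)
  })
}

# independent brute-force distance oracle: plain per-frame loops, no reuse
# of package internals
brute_pair_distance <- function(ens, chain_a, resnum_a, chain_b, resnum_b,
                                mode = "sidechain_centroid") {
  at <- ens$atoms
  sel <- function(chain, resnum) {
    rows <- which(at$chain == chain & at$resnum == resnum &
                    at$element != "H")
    if (mode == "ca") {
      rows[at$atom_name[rows] == "CA"]
    } else if (mode == "sidechain_centroid") {
      sc <- rows[!(at$atom_name[rows] %in% c("N", "CA", "C", "O", "OXT"))]
      if (length(sc) == 0) rows[at$atom_name[rows] == "CA"] else sc
    } else {
      rows
    }
  }
  ia <- sel(chain_a, resnum_a); ib <- sel(chain_b, resnum_b)
  out <- numeric(ens$frame_count)
  for (f in seq_len(ens$frame_count)) {
    if (mode == "min_heavy") {
      best <- Inf
      for (i in ia) for (j in ib) {
        d <- sqrt(sum((ens$coords[i, , f] - ens$coords[j, , f])^2))
        if (d < best) best <- d
      }
      out[f] <- best
    } else {
      ca <- colMeans(matrix(ens$coords[ia, , f], ncol = 3))
      cb <- colMeans(matrix(ens$coords[ib, , f], ncol = 3))
      out[f] <- sqrt(sum((ca - cb)^2))
    }
  }
  out
}

# independent per-compound cascade rule evaluator
brute_cascade <- function(table, stages, universe) {
  score_of <- function(cmpd, scorer, target) {
    hit <- table$score[table$compound_id == cmpd &
                         table$scorer_id == scorer &
                         table$target_id == target]
    if (length(hit) == 0) NA_real_ else hit[1]
  }
  surv <- universe
  out <- list()
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    if (st$type == "rank_top") {
      scores <- vapply(surv, score_of, 0, st$scorer, st$target)
      has <- !is.na(scores)
      ord <- order(scores[has], surv[has])
      surv <- sort(surv[has][ord][seq_len(min(st$k, sum(has)))])
      surv <- surv[order(match(surv, universe))]
    } else {
      keep <- logical(length(surv))
      for (i in seq_along(surv)) {
        c_id <- surv[i]
        if (st$type == "differential_binder") {
          sp <- score_of(c_id, st$scorer, st$positive)
          sn <- score_of(c_id, st$scorer, st$negative)
          keep[i] <- !is.na(sp) && sp < st$cutoff &&
            !(!is.na(sn) && sn < st$cutoff)
        } else {
          sc <- score_of(c_id, st$scorer, st$target)
          keep[i] <- !is.na(sc) && sc < st$cutoff
        }
      }
      surv <- surv[keep]
    }
    out[[k]] <- surv
  }
  out
}
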
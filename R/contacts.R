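# bead-level metadata shared by the contact statistics
bead_meta <- function(state) {
  n_per <- vapply(state$topologies, function(tp) tp$length, integer(1))
  list(chain = state$chain,
       pos = unlist(lapply(n_per, seq_len), use.names = FALSE),
       type = state$types,
       chain_class = state$mol_class,
       n_per = n_per)
}

#' Find inter-chain contacts in one configuration
#'
#' Two beads on *different* chains are in (potential) contact when
#' their minimum-image distance is strictly less than the sum of their
#' volume-derived contact radii. Intra-chain pairs are never reported.
#'
#' @param state a `system_state` (supplies box, chains, bead types).
#' @param ps an `hps_params` (supplies the radii).
#' @param coords optional n x 3 coordinates to analyse instead of
#'   `state$coords` (e.g. one trajectory frame).
#' @return data.frame with bead indices (`i`, `j`, global 1-based),
#'   chain ids, 1-based residue positions, bead types and the
#'   distance.
#' @export
find_contacts <- function(state, ps, coords = NULL) {
  if (is.null(coords)) coords <- state$coords
  meta <- bead_meta(state)
  radius <- param_lookup(ps, state$types, "radius")
  ct <- cpp_find_contacts(coords, state$box, radius, state$chain)
  i <- ct$i + 1L; j <- ct$j + 1L
  data.frame(i = i, j = j,
             chain_i = meta$chain[i], chain_j = meta$chain[j],
             pos_i = meta$pos[i], pos_j = meta$pos[j],
             type_i = meta$type[i], type_j = meta$type[j],
             dist = ct$dist)
}

#' Per-frame contact map of a trajectory
#'
#' Applies the radius-threshold contact criterion ([find_contacts()])
#' to every frame and stores the per-frame inter-chain contact sets
#' together with the bead metadata needed by the downstream
#' statistics ([residue_profile()], [transience_fraction()],
#' [pair_counts()], [group_contact_matrix()]).
#'
#' @param traj an `hps_trajectory`.
#' @param ps an `hps_params`.
#' @param frames optional frame subset (indices).
#' @return a `contact_map` object.
#' @export
contact_map <- function(traj, ps, frames = NULL) {
  stopifnot(inherits(traj, "hps_trajectory"))
  if (traj$n_frames < 1) stop("trajectory has no frames")
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  state <- traj$system
  meta <- bead_meta(state)
  radius <- param_lookup(ps, state$types, "radius")
  per_frame <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    ct <- cpp_find_contacts(traj$frames[, , f], traj$boxes[f, ], radius,
                            state$chain)
    per_frame[[k]] <- cbind(i = ct$i + 1L, j = ct$j + 1L)
  }
  structure(list(frames = per_frame, n_frames = length(frames),
                 frame_ids = frames, meta = meta,
                 frame_interval = traj$frame_interval,
                 n_beads = n_beads(state)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  tot <- sum(vapply(x$frames, nrow, integer(1)))
  cat(sprintf(
    "contact_map: %d frames, %.1f inter-chain contacts/frame (%d chains)\n",
    x$n_frames, tot / x$n_frames, length(x$meta$n_per)))
  invisible(x)
}

# chains selected for position-level statistics; default: every chain
# of the most common molecule class, which must share one length
select_chains <- function(cmap, chains) {
  cls <- cmap$meta$chain_class
  if (is.null(chains)) {
    major <- names(sort(table(cls), decreasing = TRUE))[1]
    chains <- which(cls == major)
  }
  len <- unique(cmap$meta$n_per[chains])
  if (length(len) != 1)
    stop("selected chains must share one sequence length")
  list(chains = chains, length = len)
}

#' Per-residue mean contacts per frame
#'
#' For each sequence position, the number of inter-chain contacts made
#' by all chain copies of that position, summed over copies and frames
#' and divided by the frame count (the per-residue profile of a
#' 120-copy slab counts all 120 copies of each residue).
#'
#' @param cmap a `contact_map`.
#' @param chains chain ids to pool (default: all chains of the most
#'   common molecule class); must share one length.
#' @return data.frame `pos`, `residue`, `mean_contacts`.
#' @export
residue_profile <- function(cmap, chains = NULL) {
  stopifnot(inherits(cmap, "contact_map"))
  sel <- select_chains(cmap, chains)
  meta <- cmap$meta
  in_sel <- meta$chain %in% sel$chains
  counts <- numeric(sel$length)
  for (fr in cmap$frames) {
    for (col in 1:2) {
      b <- fr[, col]
      b <- b[in_sel[b]]
      if (length(b))
        counts <- counts + tabulate(meta$pos[b], nbins = sel$length)
    }
  }
  first <- which(meta$chain == sel$chains[1])
  data.frame(pos = seq_len(sel$length),
             residue = bead_to_letter(meta$type[first]),
             mean_contacts = counts / cmap$n_frames)
}

#' Contact transience between consecutive frames
#'
#' The liquidity statistic: of all bead pairs in contact in a frame,
#' the percentage no longer in contact in the next frame, pooled over
#' all consecutive frame pairs
#' (`100 * sum_t broken_t / sum_t present_t`). Values near 100% mean
#' contacts almost never survive one frame interval.
#'
#' @param cmap a `contact_map` with at least 2 frames.
#' @return percentage in `[0, 100]`.
#' @export
transience_fraction <- function(cmap) {
  stopifnot(inherits(cmap, "contact_map"))
  if (cmap$n_frames < 2) stop("need at least 2 frames")
  nb <- cmap$n_beads
  keys <- lapply(cmap$frames, function(fr)
    (fr[, 1] - 1) * nb + fr[, 2])
  present <- 0; broken <- 0
  for (t in seq_len(cmap$n_frames - 1)) {
    k <- keys[[t]]
    present <- present + length(k)
    broken <- broken + sum(!(k %in% keys[[t + 1]]))
  }
  if (present == 0) return(NaN)
  100 * broken / present
}

#' Position-pair contact counts across frames
#'
#' Aggregates inter-chain contacts to sequence-position pairs over all
#' chain copies. With `mode = "frame"` (default) a position pair
#' counts at most once per frame, however many copy pairs realize it;
#' `mode = "incidence"` counts every copy pair occurrence.
#'
#' @param cmap a `contact_map`.
#' @param chains chain ids to pool (see [residue_profile()]).
#' @param mode `"frame"` or `"incidence"`.
#' @return data.frame `pos_i`, `pos_j` (`pos_i <= pos_j`), `count`.
#' @export
pair_counts <- function(cmap, chains = NULL,
                        mode = c("frame", "incidence")) {
  mode <- match.arg(mode)
  sel <- select_chains(cmap, chains)
  meta <- cmap$meta
  in_sel <- meta$chain %in% sel$chains
  L <- sel$length
  acc <- new.env(parent = emptyenv())
  tally <- numeric(0)
  for (fr in cmap$frames) {
    keep <- in_sel[fr[, 1]] & in_sel[fr[, 2]]
    if (!any(keep)) next
    p <- meta$pos[fr[keep, 1]]; q <- meta$pos[fr[keep, 2]]
    key <- (pmin(p, q) - 1) * L + pmax(p, q)
    if (mode == "frame") key <- unique(key)
    tb <- table(key)
    idx <- as.numeric(names(tb))
    old <- tally[as.character(idx)]
    old[is.na(old)] <- 0
    tally[as.character(idx)] <- old + as.numeric(tb)
  }
  if (!length(tally))
    return(data.frame(pos_i = integer(0), pos_j = integer(0),
                      count = numeric(0)))
  idx <- as.numeric(names(tally))
  data.frame(pos_i = (idx - 1) %/% L + 1, pos_j = (idx - 1) %% L + 1,
             count = as.numeric(tally), row.names = NULL)
}

#' Thresholded contact network
#'
#' Keeps the position pairs whose contact count reaches `min_count`
#' (inclusive: "at least"), the filter used to draw the interaction
#' network of a slab trajectory (>= 350 occurrences within 1,000
#' frames).
#'
#' @param counts data.frame from [pair_counts()].
#' @param min_count inclusive count threshold.
#' @param frame_count number of frames behind the counts; when
#'   `min_count > frame_count` and counting is once-per-frame no edge
#'   can pass, which yields an empty network with a warning.
#' @param chain optional `chain_topology` used to annotate nodes with
#'   residue identities.
#' @return data.frame `pos_i`, `pos_j`, `count` (plus `res_i`, `res_j`
#'   when `chain` is given), one row per edge.
#' @export
contact_network <- function(counts, min_count = 350, frame_count = 1000,
                            chain = NULL) {
  if (!is.null(frame_count) && min_count > frame_count)
    warning("min_count exceeds the frame count; network is empty")
  edges <- counts[counts$count >= min_count, , drop = FALSE]
  edges <- edges[order(-edges$count), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(chain)) {
    letters <- bead_to_letter(chain$sequence)
    edges$res_i <- letters[edges$pos_i]
    edges$res_j <- letters[edges$pos_j]
  }
  edges
}

#' Mean cross-group contact matrix
#'
#' Entry `(p, q)` is the mean number of contacts per frame between
#' position `p` of the group-a chains and position `q` of the group-b
#' chains (e.g. protein positions x RNA positions). The groups must be
#' disjoint, or identical, in which case each unordered pair is
#' counted once and split symmetrically across `(p, q)` and `(q, p)`.
#' The scalar grand total is the group pair's mean contacts per frame
#' (the "average interactions per frame" summary of a mixed system).
#'
#' @param cmap a `contact_map`.
#' @param group_a,group_b chain id vectors; chains within each group
#'   must share one length.
#' @return list with `matrix` (positions_a x positions_b) and `total`
#'   (mean contacts per frame between the groups).
#' @export
group_contact_matrix <- function(cmap, group_a, group_b) {
  stopifnot(inherits(cmap, "contact_map"))
  if (!length(group_a) || !length(group_b)) stop("empty chain group")
  identical_groups <- setequal(group_a, group_b)
  if (!identical_groups && length(intersect(group_a, group_b)))
    stop("groups must be disjoint or identical")
  la <- unique(cmap$meta$n_per[group_a])
  lb <- unique(cmap$meta$n_per[group_b])
  if (length(la) != 1 || length(lb) != 1)
    stop("chains within a group must share one sequence length")
  meta <- cmap$meta
  in_a <- meta$chain %in% group_a
  in_b <- meta$chain %in% group_b
  m <- matrix(0, la, lb)
  for (fr in cmap$frames) {
    bi <- fr[, 1]; bj <- fr[, 2]
    if (identical_groups) {
      keep <- in_a[bi] & in_a[bj]
      p <- meta$pos[bi[keep]]; q <- meta$pos[bj[keep]]
      for (k in seq_along(p)) {
        m[p[k], q[k]] <- m[p[k], q[k]] + 0.5
        m[q[k], p[k]] <- m[q[k], p[k]] + 0.5
      }
    } else {
      ab <- in_a[bi] & in_b[bj]
      p <- meta$pos[bi[ab]]; q <- meta$pos[bj[ab]]
      ba <- in_b[bi] & in_a[bj]
      p <- c(p, meta$pos[bj[ba]]); q <- c(q, meta$pos[bi[ba]])
      for (k in seq_along(p)) m[p[k], q[k]] <- m[p[k], q[k]] + 1
    }
  }
  m <- m / cmap$n_frames
  list(matrix = m, total = sum(m))
}

#' Per-class contact summary
#'
#' Mean inter-chain contacts per frame for every unordered pair of
#' molecule classes in the system (protein-protein, protein-RNA,
#' RNA-RNA), the composition summary of a mixed slab.
#'
#' @param cmap a `contact_map`.
#' @return data.frame `class_a`, `class_b`, `contacts_per_frame`.
#' @export
contact_summary <- function(cmap) {
  cls <- cmap$meta$chain_class
  meta <- cmap$meta
  ucls <- sort(unique(cls))
  combos <- list()
  for (a in seq_along(ucls)) for (b in a:length(ucls))
    combos[[length(combos) + 1]] <- c(ucls[a], ucls[b])
  bead_cls <- cls[meta$chain]
  res <- data.frame(class_a = character(0), class_b = character(0),
                    contacts_per_frame = numeric(0))
  for (cb in combos) {
    tot <- 0
    for (fr in cmap$frames) {
      ca <- bead_cls[fr[, 1]]; cbb <- bead_cls[fr[, 2]]
      tot <- tot + sum((ca == cb[1] & cbb == cb[2]) |
                         (ca == cb[2] & cbb == cb[1]))
    }
    res <- rbind(res, data.frame(class_a = cb[1], class_b = cb[2],
                                 contacts_per_frame = tot / cmap$n_frames))
  }
  res
}
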
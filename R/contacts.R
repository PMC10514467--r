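#' Per-residue contact scores between two atom groups
#'
#' Each heavy-atom pair (i in group1, j in group2) within the neighbour
#' cutoff contributes a sigmoidal weight
#' \deqn{w(d) = 1 / (1 + e^{(d - d_0)/\sigma})}
#' which is summed into the residue pair containing the atoms and averaged
#' over frames. Aggregated per-residue scores are the sum over a residue's
#' pairs. Absolute score thresholds are calibration-dependent on
#' (`d0`, `sigma`); the shipped defaults (4.0 A, 0.5 A) make a pair at
#' van-der-Waals contact contribute about half a unit.
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param group1,group2 disjoint atom-index vectors.
#' @param d0 sigmoid midpoint (A).
#' @param sigma sigmoid steepness (A).
#' @param cutoff neighbour-list cutoff (A); pairs beyond it contribute 0.
#' @param frames frame indices (default all).
#' @return a `contact_map`: list with `pairs` (data.frame `chain1`,
#'   `resno1`, `chain2`, `resno2`, `score`, frame-averaged),
#'   `residues` (per-residue aggregated scores for both sides), and the
#'   scoring parameters.
#' @export
contact_scores <- function(x, group1, group2, d0 = 4.0, sigma = 0.5,
                           cutoff = 10.0, frames = NULL) {
  if (length(intersect(group1, group2)))
    stop("group1 and group2 must be disjoint")
  top <- topology_of(x)
  heavy <- which(top$atoms$elesy != "H")
  g1 <- intersect(group1, heavy); g2 <- intersect(group2, heavy)
  if (length(g1) == 0 || length(g2) == 0)
    stop("contact groups must contain heavy atoms")
  if (is.null(frames)) frames <- seq_len(n_frames(x))
  at <- top$atoms
  key <- function(idx) paste(at$chain[idx], at$resno[idx])

  acc <- new.env(parent = emptyenv())
  for (f in frames) {
    m <- frame_xyz(x, f)
    cp <- close_pairs_cpp(m, as.integer(g1), as.integer(g2), cutoff)
    if (nrow(cp) == 0) next
    w <- 1 / (1 + exp((cp[, "d"] - d0) / sigma))
    pk <- paste(key(cp[, "i"]), "|", key(cp[, "j"]))
    s <- tapply(w, pk, sum)
    for (nm in names(s))
      assign(nm, (if (exists(nm, acc)) get(nm, acc) else 0) + s[[nm]], acc)
  }
  nms <- ls(acc)
  if (length(nms)) {
    score <- vapply(nms, get, numeric(1), envir = acc) / length(frames)
    parts <- do.call(rbind, strsplit(nms, " \\| "))
    lhs <- do.call(rbind, strsplit(parts[, 1], " "))
    rhs <- do.call(rbind, strsplit(parts[, 2], " "))
    pairs <- data.frame(chain1 = lhs[, 1], resno1 = as.integer(lhs[, 2]),
                        chain2 = rhs[, 1], resno2 = as.integer(rhs[, 2]),
                        score = unname(score))
    pairs <- pairs[order(pairs$chain1, pairs$resno1, pairs$chain2,
                         pairs$resno2), ]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(chain1 = character(), resno1 = integer(),
                        chain2 = character(), resno2 = integer(),
                        score = numeric())
  }
  res1 <- aggregate_side(pairs, "chain1", "resno1")
  res2 <- aggregate_side(pairs, "chain2", "resno2")
  residues <- rbind(res1, res2)
  structure(list(pairs = pairs, residues = residues,
                 d0 = d0, sigma = sigma, cutoff = cutoff,
                 n_frames = length(frames)),
            class = "contact_map")
}

aggregate_side <- function(pairs, chain_col, resno_col) {
  if (nrow(pairs) == 0)
    return(data.frame(chain = character(), resno = integer(),
                      score = numeric()))
  df <- data.frame(chain = pairs[[chain_col]], resno = pairs[[resno_col]],
                   score = pairs$score)
  out <- aggregate(score ~ chain + resno, data = df, FUN = sum)
  out[order(out$chain, out$resno), ]
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", nrow(x$pairs), "residue pairs,",
      nrow(x$residues), "residues (d0 =", x$d0, "A, sigma =", x$sigma,
      "A, averaged over", x$n_frames, "frames)\n")
  invisible(x)
}

#' Interface residues above a contact-score threshold
#'
#' Residues whose aggregated frame-averaged contact score exceeds the
#' threshold -- the set rendered as the interface footprint on surface
#' maps (threshold 1 with the shipped score calibration).
#'
#' @param cm a `contact_map`.
#' @param threshold score threshold (>= 0).
#' @return data.frame with `chain`, `resno`, `score` for residues with
#'   score > threshold.
#' @export
interface_residues <- function(cm, threshold = 1.0) {
  stopifnot(inherits(cm, "contact_map"))
  if (threshold < 0) stop("threshold must be >= 0")
  out <- cm$residues[cm$residues$score > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
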
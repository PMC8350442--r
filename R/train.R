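# Sequence-set preparation for training.

#' Drop the longest sequences and sort the rest by length
#'
#' Removes the `ceiling(drop_frac * N)` longest sequences (extreme lengths
#' force wasteful padding) and sorts the remainder by length, ascending and
#' stable. Padding to the longest retained length happens with zero
#' vectors at batch assembly, with true lengths recorded; the model reads
#' its output at the last true step, so padding never leaks into the
#' prediction.
#'
#' @param fseqs list of [feature_sequence()].
#' @param drop_frac fraction of longest sequences to remove (default 0.02).
#' @return list with `sequences` (sorted survivors), `lengths`, `dropped`
#'   (the removed sequences) and `max_len` (longest retained length).
#' @export
prepare_sequences <- function(fseqs, drop_frac = 0.02) {
  if (!length(fseqs))
    stop_gpn("gpn_data_error", "no sequences to prepare")
  len <- vapply(fseqs, function(s) nrow(s$features), 0L)
  n_drop <- min(ceiling(drop_frac * length(fseqs)), length(fseqs) - 1L)
  # only sequences strictly longer than the longest retained length are
  # removed: a set of equal-length sequences loses nothing
  drop_idx <- integer(0)
  if (n_drop > 0) {
    ord <- order(len, decreasing = TRUE)
    cutoff <- len[ord[n_drop + 1L]]
    drop_idx <- ord[seq_len(n_drop)][len[ord[seq_len(n_drop)]] > cutoff]
  }
  keep <- setdiff(seq_along(fseqs), drop_idx)
  if (!length(keep))
    stop_gpn("gpn_data_error", "all sequences dropped")
  keep <- keep[order(len[keep])]            # ascending, stable
  list(sequences = fseqs[keep], lengths = len[keep],
       dropped = fseqs[drop_idx], max_len = max(len[keep]))
}

#' Balance classes by random undersampling
#'
#' Every class is undersampled to the minority-class count; deterministic
#' given `seed`. Surviving sequences keep their input order.
#'
#' @param fseqs list of [feature_sequence()].
#' @param seed integer seed.
#' @param n_classes number of classes that must all be present (default 3).
#' @return balanced list of [feature_sequence()].
#' @export
balance_classes <- function(fseqs, seed = 1L, n_classes = 3L) {
  y <- vapply(fseqs, `[[`, 0L, "label")
  counts <- vapply(0:(n_classes - 1L), function(k) sum(y == k), 0L)
  absent <- which(counts == 0L) - 1L
  if (length(absent))
    stop_gpn("gpn_data_error", "class(es) absent from training data: %s (%s)",
             paste(absent, collapse = ", "),
             paste(EXPERTISE_LEVELS[absent + 1L], collapse = ", "))
  m <- min(counts)
  keep <- with_local_seed(derive_seed(seed, "balance"), {
    unlist(lapply(0:(n_classes - 1L), function(k) {
      idx <- which(y == k)
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }))
  })
  fseqs[sort(keep)]
}
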
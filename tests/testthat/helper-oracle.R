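# Brute-force reference implementation of the windowed crossover-validation
# rule: for every pair of consecutive informative (non-missing) markers with
# differing calls, gather up to `window` informative calls ending at the left
# marker and starting at the right marker and require each side to be
# uniform. A direct transcription of the rule, with none of the run-length
# shortcuts of the production caller.
oracle_call <- function(calls, window = 3L) {
  obs <- which(!is.na(calls))
  out <- list()
  if (length(obs) >= 2) {
    for (k in 2:length(obs)) {
      i <- obs[k - 1L]
      j <- obs[k]
      a <- calls[i]
      b <- calls[j]
      if (a == b) next
      left_side <- obs[obs <= i]
      left_side <- tail(left_side, window)
      right_side <- obs[obs >= j]
      right_side <- head(right_side, window)
      if (all(calls[left_side] == a) && all(calls[right_side] == b)) {
        score <- if ((a == "AA" && b == "BB") || (a == "BB" && b == "AA")) 2L else 1L
        out[[length(out) + 1L]] <- c(i, j, score)
      }
    }
  }
  if (length(out) == 0) {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("left", "right", "score")))
  } else {
    m <- do.call(rbind, out)
    colnames(m) <- c("left", "right", "score")
    m
  }
}

# production caller output in the oracle's matrix form
caller_as_matrix <- function(calls, window = 3L) {
  ev <- call_crossover_sequence(calls, caller_config(window = window))
  m <- cbind(left = ev$left, right = ev$right, score = ev$score)
  storage.mode(m) <- "integer"
  m
}
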
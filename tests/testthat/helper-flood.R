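# 4-neighbour flood fill used by the geometry tests
flood_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask & lab == 0L)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    H <- nrow(mask)
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% H + 1L
      j <- (p - 1L) %/% H + 1L
      for (q in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (q[1] < 1 || q[1] > H || q[2] < 1 || q[2] > ncol(mask)) next
        idx <- q[1] + H * (q[2] - 1L)
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- cur
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}

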
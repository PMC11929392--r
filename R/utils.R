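# Cosine similarity of two vectors; NA (with zero_flag attr handled by
# callers) when either vector is all-zero.
.cosine <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Cosine similarity of a query against every row of a matrix.
.cosine_rows <- function(M, v) {
  nv <- sqrt(sum(v^2))
  nr <- sqrt(rowSums(M^2))
  out <- as.vector(M %*% v) / (nr * nv)
  out[nr == 0 | nv == 0] <- NA_real_
  out
}
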
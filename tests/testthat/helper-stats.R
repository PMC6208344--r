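# independent brute-force reference for the two-stage step-up procedure,
# written directly from the published definition
bky_reference <- function(p, Q = 0.05) {
  m <- length(p)
  qp <- Q / (1 + Q)
  step_up <- function(level) {
    s <- sort(p)
    below <- which(s <= level * seq_len(m) / m)
    if (length(below)) max(below) else 0L
  }
  r1 <- step_up(qp)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  k <- step_up(qp * m / (m - r1))
  p <= (sort(p)[k] + 1e-15) & k > 0
}
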
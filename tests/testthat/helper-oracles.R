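## Independent brute-force oracles used to freeze expected values.

## binomial upper tail P(X >= k) by direct summation of the mass function
bruteBinomTail <- function(k, N, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:N, function(x) dbinom(x, N, p0), numeric(1)))
}

## two-sided Fisher p by hypergeometric enumeration over all tables with
## the observed margins
bruteFisher2 <- function(ka, na, kb, nb) {
  K <- ka + kb
  xs <- max(0, K - nb):min(K, na)
  probs <- dhyper(xs, na, nb, K)
  pObs <- dhyper(ka, na, nb, K)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## exhaustive PWM window scoring on both strands (naive loops)
brutePwmScan <- function(seq, motif, threshold) {
  lo <- rbind(motif$logodds, N = 0)
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- c(A = 1, C = 2, G = 3, T = 4)[chars]
  code[is.na(code)] <- 5
  L <- ncol(lo)
  n <- length(code)
  out <- NULL
  if (n >= L) {
    rc <- rev(c(4, 3, 2, 1, 5)[code])
    for (i in 1:(n - L + 1)) {
      sF <- sum(lo[cbind(code[i:(i + L - 1)], 1:L)])
      if (sF >= threshold)
        out <- rbind(out, data.frame(position = i, strand = "+", score = sF))
      sR <- sum(lo[cbind(rc[i:(i + L - 1)], 1:L)])
      if (sR >= threshold)
        out <- rbind(out, data.frame(position = n - L + 2 - i, strand = "-",
                                     score = sR))
    }
  }
  if (is.null(out))
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- out[order(out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

## two-sided t-test p-value by numerical integration of the t density
bruteTPvalue <- function(tstat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
}

## iterative proportional fitting oracle (plain loop implementation)
bruteIPF <- function(m, iters) {
  for (i in seq_len(iters)) {
    rs <- rowSums(m)
    b <- rs / mean(rs[rs > 0])
    b[b == 0] <- 1
    m <- m / outer(b, b)
  }
  m
}
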
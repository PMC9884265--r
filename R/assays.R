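#' Relative interaction frequency from 3C-qPCR Ct tables
#'
#' Per reaction `RIF_raw = E^-(Ct_target - Ct_norm)` with amplification
#' efficiency `E` (2 by default), where `Ct_norm` comes from a region uncut
#' by the restriction enzyme and normalizes the template amount (RIF is
#' invariant to adding a constant to both Ct values). Technical replicates
#' are averaged first, then biological replicates; the output is scaled so
#' that the reference group's mean is 1 for each loop.
#'
#' @param t data.frame with columns `genotype`, `condition`, `loop`,
#'   `bioRep`, `techRep`, `Ct_target`, `Ct_norm`.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @param refGenotype,refCondition Reference group anchoring the scale
#'   (default WT at 0h).
#' @return A data.frame per (genotype, condition, loop): `mean`, `sd`, `n`
#'   (biological replicates), plus `bioValues` kept as an attribute
#'   `"perBio"` data.frame for downstream testing.
#' @export
relativeInteractionFrequency <- function(t, efficiency = 2,
                                         refGenotype = "WT",
                                         refCondition = "0h") {
  miss <- is.na(t$Ct_norm) | is.na(t$Ct_target)
  if (any(miss)) {
    warning(sum(miss), " reaction(s) without normalization Ct dropped")
    t <- t[!miss, , drop = FALSE]
  }
  t$rif <- efficiency^(-(t$Ct_target - t$Ct_norm))
  ## technical replicates first
  bio <- aggregate(rif ~ genotype + condition + loop + bioRep, data = t, FUN = mean)
  ref <- aggregate(rif ~ loop, data = bio[bio$genotype == refGenotype &
                                            bio$condition == refCondition, ],
                   FUN = mean)
  refScale <- setNames(ref$rif, ref$loop)
  bio$rif <- bio$rif / refScale[bio$loop]
  out <- do.call(rbind, lapply(split(bio, list(bio$genotype, bio$condition,
                                               bio$loop), drop = TRUE),
    function(g) data.frame(genotype = g$genotype[1], condition = g$condition[1],
                           loop = g$loop[1], mean = mean(g$rif),
                           sd = sd(g$rif), n = nrow(g))))
  out <- out[order(out$loop, out$genotype, out$condition), ]
  rownames(out) <- NULL
  attr(out, "perBio") <- bio
  out
}

#' Normalized dual-luciferase activity
#'
#' Per replicate the firefly/renilla ratio `LUC/REN`; per construct the mean
#' of these ratios divided by the control construct's mean ratio, so the
#' control normalizes to exactly 1 and the output is invariant to any
#' common scaling of the REN channel.
#'
#' @param t data.frame with columns `construct`, `replicate`, `LUC`, `REN`.
#' @param control Name of the control construct (default `"mini35S"`).
#' @return A data.frame per construct: `mean`, `sd`, `n`, with per-replicate
#'   normalized ratios in attribute `"perRep"`.
#' @export
luciferaseActivity <- function(t, control = "mini35S") {
  if (!control %in% t$construct) stop("control construct absent: ", control)
  stopifnot(all(t$REN > 0))
  t$ratio <- t$LUC / t$REN
  ctrlMean <- mean(t$ratio[t$construct == control])
  t$norm <- t$ratio / ctrlMean
  out <- do.call(rbind, lapply(split(t, t$construct), function(g)
    data.frame(construct = g$construct[1], mean = mean(g$norm),
               sd = sd(g$norm), n = nrow(g))))
  out <- out[order(out$construct != control, out$construct), ]
  rownames(out) <- NULL
  attr(out, "perRep") <- t
  out
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Equal-variance form: `df = n_a + n_b - 2`, p-value from the t
#' distribution (one- or two-sided). Swapping the groups flips the sign of
#' `t` and leaves `p` unchanged. With zero pooled variance, equal means
#' give `t = 0, p = 1`; unequal means give `p` at the double-precision
#' minimum with a flag. Welch's unequal-variance form is available via
#' `welch = TRUE`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param sides `"two"` (default) or `"one"` (alternative: mean(a) <
#'   mean(b) if the observed difference is negative, else >).
#' @param welch Use Welch's t instead of the pooled form.
#' @return A list with `t`, `df`, `p`, and `flag` (`"zero_variance"` when
#'   applicable).
#' @export
twoSampleT <- function(a, b, sides = c("two", "one"), welch = FALSE) {
  sides <- match.arg(sides)
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  if (welch) {
    ht <- t.test(a, b, var.equal = FALSE)
    tt <- unname(ht$statistic); df <- unname(ht$parameter)
  } else {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    df <- na + nb - 2
    if (sp2 == 0) {
      if (mean(a) == mean(b))
        return(list(t = 0, df = df, p = 1, flag = NULL))
      return(list(t = sign(mean(a) - mean(b)) * Inf, df = df,
                  p = .Machine$double.xmin, flag = "zero_variance"))
    }
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p <- if (sides == "two") 2 * pt(-abs(tt), df) else pt(-abs(tt), df)
  list(t = tt, df = df, p = p, flag = NULL)
}
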
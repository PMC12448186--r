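## Independent oracles used across the suite. Each one is deliberately a
## different computation path from the package function it checks.

## Ordinary pooled two-sample t (equal-variance) via stats::t.test per gene.
pooled_t_oracle <- function(m, idx1, idx2) {
    t(vapply(seq_len(nrow(m)), function(g) {
        tt <- t.test(m[g, idx1], m[g, idx2], var.equal = TRUE)
        c(t = unname(tt$statistic), p = tt$p.value,
          diff = unname(tt$estimate[1] - tt$estimate[2]))
    }, c(t = 0, p = 0, diff = 0)))
}

## Hand application of the BH step-up rule.
bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

## Two-sided Fisher p by full enumeration of all tables with the observed
## margins, summing hypergeometric probabilities <= that of the observed
## table (relative tolerance 1 + 1e-7, the classical convention).
fisher_enum_oracle <- function(a, b, c, d) {
    m <- a + c; n2 <- b + d; k <- a + b
    lo <- max(0, k - n2); hi <- min(k, m)
    x <- lo:hi
    pr <- dhyper(x, m, n2, k)
    pobs <- dhyper(a, m, n2, k)
    sum(pr[pr <= pobs * (1 + 1e-7)])
}

## Mean shared-DE count under label shuffling of the first species.
perm_shared_oracle <- function(de1, de2, B = 20000, seed = 1) {
    stopifnot(length(de1) == length(de2))
    set.seed(seed)
    mean(vapply(seq_len(B), function(i) sum(sample(de1) & de2), 0))
}

## Minimal-total-length embedding of the quartet on the real line with
## topology ((o1, o2), (m, p)). The outgroup Steiner point is the L1
## median of (o1, o2, x2); the focal Steiner point x2 is scanned over the
## breakpoints of the piecewise-linear objective (the four data values).
## Only well-posed for rooted configurations (both outgroups on one side
## of both focal values); a tie across minimisers aborts.
line_embed_oracle <- function(m, p, o1, o2) {
    f <- function(x2) {
        x1 <- median(c(o1, o2, x2))
        abs(m - x2) + abs(p - x2) + abs(x2 - x1) +
            abs(o1 - x1) + abs(o2 - x1)
    }
    cand <- c(m, p, o1, o2)
    vals <- vapply(cand, f, 0)
    best <- cand[vals <= min(vals) + 1e-12]
    bm <- abs(m - best); bp <- abs(p - best)
    stopifnot(diff(range(bm)) < 1e-9, diff(range(bp)) < 1e-9)
    c(b_m = bm[1], b_p = bp[1])
}

## Draw gene variances from the scaled inverse-chi-square hierarchy:
## sigma^2 ~ s0 * d0 / chisq(d0), s^2 | sigma^2 ~ sigma^2 * chisq(dg)/dg.
rvar_from_prior <- function(n, d0, s0, dg) {
    sigma2 <- s0 * d0 / rchisq(n, d0)
    sigma2 * rchisq(n, dg) / dg
}
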
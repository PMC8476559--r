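# Independent oracles and shared fixtures. Everything here is deliberately
# written from first principles (different code paths than the package).

# published dCN count tables shipped with the package
printedTables <- function() {
  readCountTables(system.file("extdata", "sle_dcn_counts.csv",
                              package = "mrcCNV"))
}

printedMatrix <- function(id) tableCounts(printedTables()[[id]])

# two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration
oracleFisher2x2 <- function(m) {
  cs <- colSums(m); n1 <- sum(m[1, ])
  xs <- max(0, n1 - cs[2]):min(cs[1], n1)
  probs <- stats::dhyper(xs, cs[1], cs[2], n1)
  pObs <- stats::dhyper(m[1, 1], cs[1], cs[2], n1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Freeman-Halton p for a 2xk table by recursive enumeration of the first row
oracleFisher2xk <- function(m) {
  cs <- colSums(m); rs <- rowSums(m); N <- sum(m)
  logProb <- function(r1) {
    cells <- c(r1, cs - r1)
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(cells))
  }
  lObs <- logProb(m[1, ])
  total <- 0
  recurse <- function(j, prefix, left) {
    if (j == length(cs)) {
      if (left <= cs[j]) {
        lp <- logProb(c(prefix, left))
        if (lp <= lObs + log(1 + 1e-7)) total <<- total + exp(lp)
      }
      return(invisible(NULL))
    }
    for (v in 0:min(cs[j], left)) recurse(j + 1, c(prefix, v), left - v)
  }
  recurse(1, integer(0), rs[1])
  total
}

# dense grid-search maximum likelihood over the haplotype-class simplex
oracleGridML <- function(nk, AMax, step = 0.005) {
  nk <- c(nk, rep(0, 2 * AMax + 1 - length(nk)))
  ll <- function(q) {
    pk <- sapply(0:(2 * AMax), function(k) {
      a <- max(0, k - AMax):min(AMax, k)
      sum(q[a + 1] * q[k - a + 1])
    })
    i <- nk > 0
    if (any(pk[i] <= 0)) return(-Inf)
    sum(nk[i] * log(pk[i]))
  }
  if (AMax == 1) {
    q0 <- seq(0, 1, step)
    lls <- vapply(q0, function(x) ll(c(x, 1 - x)), numeric(1))
    best <- q0[which.max(lls)]
    return(list(q = c(best, 1 - best), loglik = max(lls)))
  }
  stopifnot(AMax == 2)
  grid <- expand.grid(q0 = seq(0, 1, step), q1 = seq(0, 1, step))
  grid <- grid[grid$q0 + grid$q1 <= 1 + 1e-12, ]
  q0 <- grid$q0; q1 <- grid$q1; q2 <- pmax(0, 1 - q0 - q1)
  P <- cbind(q0^2, 2 * q0 * q1, q1^2 + 2 * q0 * q2, 2 * q1 * q2, q2^2)
  occ <- which(nk > 0)
  lls <- as.vector(log(pmax(P[, occ, drop = FALSE], 1e-300)) %*% nk[occ])
  lls[apply(P[, occ, drop = FALSE] <= 0, 1, any)] <- -Inf
  i <- which.max(lls)
  list(q = c(q0[i], q1[i], q2[i]), loglik = lls[i])
}

binomSE <- function(p, n) sqrt(p * (1 - p) / n)

# small noiseless SummarizedExperiment of dCN calls built directly
makeCallSet <- function(dcnByGroup, gene = "G1") {
  # dcnByGroup: list(control = vector of dCN, case = vector of dCN)
  dcn <- c(dcnByGroup$control, dcnByGroup$case)
  n <- length(dcn)
  m <- matrix(as.integer(dcn), nrow = 1,
              dimnames = list(gene, sprintf("s%03d", seq_len(n))))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(dCN = m, qcPass = matrix(TRUE, 1, n,
                                           dimnames = dimnames(m))),
    colData = S4Vectors::DataFrame(
      group = rep(c("control", "case"),
                  c(length(dcnByGroup$control), length(dcnByGroup$case))),
      row.names = colnames(m)))
}
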
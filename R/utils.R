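#' Derive a child seed from a master seed and a stage label
#'
#' Every stochastic stage of the pipeline draws its own seed from the run's
#' master seed and a short stage name, so that stages can be re-run or
#' reordered without perturbing each other's random streams.
#'
#' The rule is a plain polynomial string hash folded into the master seed,
#' reduced modulo 2^31 - 1 (a Mersenne prime, so distinct stage names rarely
#' collide). All arithmetic stays below 2^53 and is exact in doubles.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"cohort/rep3"`.
#' @return a positive integer seed, strictly less than 2^31.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647
  h <- as.double(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h + 1)
}

#' Largest-remainder apportionment
#'
#' Splits an integer `total` across groups in proportion to `props`,
#' guaranteeing the parts sum to `total`. Each group first receives the floor
#' of its exact share; leftover units go to the groups with the largest
#' fractional remainders, earlier groups winning ties. This deterministic rule
#' reproduces the benchmark's per-stratum/per-class count tables exactly
#' (e.g. 34/33 and 16/17 at n = 100 balanced).
#'
#' @param total non-negative integer to split.
#' @param props non-negative weights, at least one positive.
#' @return integer vector of the same length as `props`, summing to `total`.
#' @export
apportion <- function(total, props) {
  stopifnot(total >= 0, length(props) >= 1, all(props >= 0), sum(props) > 0)
  share <- total * props / sum(props)
  base <- floor(share)
  left <- round(total - sum(base))
  if (left > 0) {
    rem <- share - base
    # stable order: largest remainder first, ties by original position
    pick <- order(-rem, seq_along(rem))[seq_len(left)]
    base[pick] <- base[pick] + 1
  }
  as.integer(base)
}

# Internal: stop unless x is a single finite number
assert_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Internal: sample skewness (g1) and excess kurtosis (g2), moment definitions
sample_skew_kurt <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  c(skewness = g1, excess_kurtosis = g2)
}
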
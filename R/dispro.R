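#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a d) / (b c)`; the 95% CI is
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell
#' the statistic (or its CI) is undefined and returned as `NA` -- no silent
#' continuity correction; set `correction = "haldane"` to add 0.5 to every
#' cell instead.
#'
#' @param a,b,c_,d cell counts (vectorized): target drug & target event,
#'   target drug & other events, other drugs & target event, other drugs &
#'   other events.
#' @param correction `"none"` (default) or `"haldane"`.
#' @param conf_z normal quantile for the CI (1.96 for 95%).
#' @return `data.table` with `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_with_ci <- function(a, b, c_, d, correction = c("none", "haldane"),
                        conf_z = 1.96) {
  correction <- match.arg(correction)
  if (correction == "haldane") {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  ror <- ifelse(b > 0 & c_ > 0, (a * d) / (b * c_), NA_real_)
  ok <- a > 0 & b > 0 & c_ > 0 & d > 0
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c_ + 1 / d), NA_real_)
  data.table::data.table(
    ror = ror,
    ror_lo = ifelse(ok, exp(log(ror) - conf_z * se), NA_real_),
    ror_hi = ifelse(ok, exp(log(ror) + conf_z * se), NA_real_))
}

#' Proportional reporting ratio with chi-squared statistic
#'
#' `PRR = (a / (a+b)) / (c / (c+d))`, undefined when `c = 0`. The
#' chi-squared statistic is the Yates-continuity-corrected Pearson statistic
#' on the 2x2 table (the convention in the spontaneous-report literature);
#' `correction = "none"` gives the uncorrected Pearson statistic.
#'
#' @inheritParams ror_with_ci
#' @param correction `"yates"` (default) or `"none"`.
#' @return `data.table` with `prr`, `chi2`.
#' @export
prr_with_chi2 <- function(a, b, c_, d, correction = c("yates", "none")) {
  correction <- match.arg(correction)
  n1 <- a + b
  n0 <- c_ + d
  prr <- ifelse(n1 > 0 & c_ > 0 & n0 > 0, (a / n1) / (c_ / n0), NA_real_)
  N <- a + b + c_ + d
  m1 <- a + c_
  m0 <- b + d
  denom <- as.numeric(n1) * n0 * m1 * m0
  dev <- abs(as.numeric(a) * d - as.numeric(b) * c_)
  if (correction == "yates") dev <- pmax(dev - N / 2, 0)
  chi2 <- ifelse(denom > 0, N * dev^2 / denom, NA_real_)
  data.table::data.table(prr = prr, chi2 = chi2)
}

#' BCPNN information component with lower credible bound
#'
#' The information component `IC = log2(O/E)` measures how much more often a
#' drug-event pair is reported than expected under independence, with
#' Bayesian shrinkage toward 0 for small counts. Two variants:
#'
#' * `"noren"` (default): the shrunk observed/expected form
#'   `IC = log2((a + 0.5) / (E + 0.5))`, with `IC025` the 2.5th percentile
#'   of `log2(lambda)` under the posterior
#'   `lambda * (E + 0.5) ~ Gamma(a + 0.5)` -- a gamma tail quantile, no
#'   normal approximation.
#' * `"bate"`: the original closed-form posterior moments of the IC under
#'   independent Beta/Dirichlet priors on the cell probabilities, with
#'   `IC025 = E(IC) - 1.96 sqrt(V(IC))`.
#'
#' Defined for `a = 0`.
#'
#' @inheritParams ror_with_ci
#' @param variant `"noren"` or `"bate"`.
#' @return `data.table` with `ic`, `ic025`.
#' @export
bcpnn_ic <- function(a, b, c_, d, variant = c("noren", "bate")) {
  variant <- match.arg(variant)
  N <- as.numeric(a) + b + c_ + d
  E <- (as.numeric(a) + b) * (as.numeric(a) + c_) / N
  if (variant == "noren") {
    ic <- log2((a + 0.5) / (E + 0.5))
    ic025 <- log2(stats::qgamma(0.025, shape = a + 0.5, rate = E + 0.5))
    return(data.table::data.table(ic = ic, ic025 = ic025))
  }
  # Bate et al. (1998) closed-form moments; priors alpha1 = beta1 = 1,
  # alpha = beta = 2, gamma11 = 1 (uniform on margins and joint).
  n11 <- as.numeric(a)
  n1. <- n11 + b
  n.1 <- n11 + c_
  a1 <- 1; b1 <- 1; aa <- 2; bb <- 2; g11 <- 1
  g <- g11 * (N + aa) * (N + bb) / ((n1. + a1) * (n.1 + b1))
  eic <- log2((n11 + g11) * (N + aa) * (N + bb) /
                ((N + g) * (n1. + a1) * (n.1 + b1)))
  vic <- ((N - n11 + g - g11) / ((n11 + g11) * (1 + N + g)) +
            (N - n1. + aa - a1) / ((n1. + a1) * (1 + N + aa)) +
            (N - n.1 + bb - b1) / ((n.1 + b1) * (1 + N + bb))) / log(2)^2
  data.table::data.table(ic = eic, ic025 = eic - 1.96 * sqrt(vic))
}

#' Apply the conventional per-algorithm signal criteria
#'
#' * ROR: `a >= 3` and lower 95% CI bound `> 1`
#' * PRR: `a >= 3`, `PRR >= 2` and `chi-squared >= 4`
#' * BCPNN: `IC025 > 0` (strict)
#' * MGPS: `EBGM05 > 2`
#' * combined: all four (the most conservative detection rule)
#'
#' An undefined statistic yields `FALSE` for its flag.
#'
#' @param results `data.table` with columns `a` (or `n`), `ror_lo`, `prr`,
#'   `chi2`, `ic025`, `ebgm05`.
#' @param thresholds named list overriding any of `min_n` (3), `prr` (2),
#'   `chi2` (4), `ic025` (0), `ebgm05` (2).
#' @return the input with logical columns `flag_ror`, `flag_prr`, `flag_ic`,
#'   `flag_ebgm`, `flag_all` added.
#' @export
apply_signal_criteria <- function(results, thresholds = list()) {
  th <- utils::modifyList(list(min_n = 3, prr = 2, chi2 = 4, ic025 = 0,
                               ebgm05 = 2), thresholds)
  dt <- data.table::as.data.table(results)
  nn <- if ("a" %in% names(dt)) dt$a else dt$n
  dt[, flag_ror := !is.na(ror_lo) & nn >= th$min_n & ror_lo > 1]
  dt[, flag_prr := !is.na(prr) & !is.na(chi2) & nn >= th$min_n &
       prr >= th$prr & chi2 >= th$chi2]
  dt[, flag_ic := !is.na(ic025) & ic025 > th$ic025]
  dt[, flag_ebgm := !is.na(ebgm05) & ebgm05 > th$ebgm05]
  dt[, flag_all := flag_ror & flag_prr & flag_ic & flag_ebgm]
  dt[]
}

#' Full disproportionality statistics for a set of contingency tables
#'
#' Computes ROR + CI, PRR + chi-squared, BCPNN IC + IC025 and MGPS
#' EBGM + EBGM05 per stratum, then the signal flags. The MGPS prior should
#' be fitted database-wide (see [mgps_fit_prior()]); when `prior` is `NULL`
#' it is fitted on the supplied tables.
#'
#' @param tables output of [build_contingency_tables()].
#' @param prior an `mgps_prior`, or `NULL` to fit on `tables`.
#' @param ror_correction,chi2_correction,ic_variant variant switches, see
#'   [ror_with_ci()], [prr_with_chi2()], [bcpnn_ic()].
#' @param thresholds see [apply_signal_criteria()].
#' @return `data.table`: `stratum`, `n`, the ten statistics, the flags.
#' @export
signal_stats <- function(tables, prior = NULL,
                         ror_correction = "none",
                         chi2_correction = "yates",
                         ic_variant = "noren",
                         thresholds = list()) {
  dt <- data.table::as.data.table(tables)
  stopifnot(all(c("stratum", "a", "b", "c_", "d") %in% names(dt)))
  if (is.null(prior)) prior <- mgps_fit_prior(dt$a, dt$E)
  out <- data.table::data.table(stratum = dt$stratum, n = dt$a)
  out <- cbind(out, ror_with_ci(dt$a, dt$b, dt$c_, dt$d,
                                correction = ror_correction))
  out <- cbind(out, prr_with_chi2(dt$a, dt$b, dt$c_, dt$d,
                                  correction = chi2_correction))
  out <- cbind(out, bcpnn_ic(dt$a, dt$b, dt$c_, dt$d, variant = ic_variant))
  out <- cbind(out, mgps_ebgm(dt$a, dt$E, prior))
  out[, a := n]
  out <- apply_signal_criteria(out, thresholds)
  out[, a := NULL]
  out[]
}
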
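new_test_result <- function(name, statistic, z, p, method, n_effective,
                            extra = list()) {
  structure(c(list(statistic_name = name, statistic = statistic, z = z,
                   p_two_tailed = p, method = method,
                   n_effective = n_effective), extra),
            class = "mt_test_result")
}

#' @export
print.mt_test_result <- function(x, ...) {
  z_txt <- if (is.na(x$z)) "" else sprintf(", Z = %.3f", x$z)
  cat(sprintf("%s = %.4g%s, two-tailed p = %.3f (%s, n = %d)\n",
              x$statistic_name, x$statistic, z_txt, x$p_two_tailed,
              x$method, x$n_effective))
  invisible(x)
}

# Exact null distribution of W+ for signed ranks r (midranks allowed):
# convolution over inclusion/exclusion of each rank. Ranks are doubled to
# make midranks integral. Returns P(W+ = w/2) on support 0..sum(r).
wplus_distribution <- function(r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
    f <- g
  }
  f / 2^length(r2)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Signed ranks on `|post - pre|` with midranks for ties; zero differences
#' (below `zero_tol`) are dropped. The asymptotic statistic is
#' `Z = (min(W+, W-) - n(n+1)/4) / sigma` with the tie-corrected variance
#' and no continuity correction; the exact two-tailed p enumerates the
#' null distribution of `W+` over all 2^n sign assignments (n <= 25).
#' With seven pairs and all differences of one sign this gives
#' Z = -2.366 and exact p = 2/128 = 0.0156.
#'
#' @param pre,post Paired measurements, equal length. Alternatively pass a
#'   single list with `pre` and `post` elements as `pre`.
#' @param method `"auto"` (exact when n <= 25), `"exact"` or
#'   `"asymptotic"`.
#' @param zero_tol Differences with absolute value below this are treated
#'   as zero and dropped.
#' @return An `mt_test_result` with `statistic` = W+ (and `w_minus`,
#'   `z`, `p_two_tailed`, `method`, `n_effective`).
#' @export
wilcoxon_signed_rank <- function(pre, post = NULL,
                                 method = c("auto", "exact", "asymptotic"),
                                 zero_tol = 1e-12) {
  method <- match.arg(method)
  if (is.null(post)) { post <- pre$post; pre <- pre$pre }
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[abs(d) > zero_tol]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (min(w_plus, w_minus) - mu) / sqrt(sigma2)
  use_exact <- switch(method,
    auto = n <= 25, exact = TRUE, asymptotic = FALSE)
  if (use_exact && n > 25)
    stop("exact enumeration supported for n <= 25")
  if (use_exact) {
    f <- wplus_distribution(r)
    support <- (seq_along(f) - 1) / 2
    p <- sum(f[abs(support - mu) >= abs(w_plus - mu) - 1e-9])
    meth <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    meth <- "asymptotic"
  }
  new_test_result("W+", w_plus, z, min(p, 1), meth, n,
                  extra = list(w_minus = w_minus))
}

# All permutations of 1..n (n small): insert n into every position of
# each (n-1)-permutation.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (s in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1
    out[[k]] <- append(s, n, after = pos)
  }
  out
}

kendall_counts <- function(x, y) {
  n <- length(x)
  C <- 0L; D <- 0L; tx <- 0L; ty <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1L
    else if (b == 0) ty <- ty + 1L
    else if (a == b) C <- C + 1L
    else D <- D + 1L
  }
  # pairs tied in x (including both-tied) / tied in y, for tau-b denominators
  Tx <- sum(choose(table(x), 2))
  Ty <- sum(choose(table(y), 2))
  list(C = C, D = D, Tx = Tx, Ty = Ty, n0 = choose(n, 2))
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected tau from direct concordant/discordant pair counts:
#' `tau_b = (C - D) / sqrt((n0 - Tx)(n0 - Ty))`. The exact two-tailed p
#' enumerates all permutations of `y` for n <= 8; larger samples use the
#' asymptotic normal approximation
#' `z = 3(C - D) / sqrt(n(n-1)(2n+5)/2)`.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @param method `"auto"` (exact when n <= 8), `"exact"` or
#'   `"asymptotic"`.
#' @return An `mt_test_result` with `statistic` = tau-b.
#' @export
kendall_tau_b <- function(x, y, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("tau-b undefined for constant input")
  k <- kendall_counts(x, y)
  tau <- (k$C - k$D) / sqrt((k$n0 - k$Tx) * (k$n0 - k$Ty))
  z <- 3 * (k$C - k$D) / sqrt(n * (n - 1) * (2 * n + 5) / 2)
  use_exact <- switch(method, auto = n <= 8, exact = TRUE,
                      asymptotic = FALSE)
  if (use_exact && n > 8) stop("exact enumeration supported for n <= 8")
  if (use_exact) {
    perms <- all_perms(n)
    tau_null <- vapply(perms, function(p) {
      kp <- kendall_counts(x, y[p])
      (kp$C - kp$D) / sqrt((kp$n0 - kp$Tx) * (kp$n0 - kp$Ty))
    }, numeric(1))
    p <- mean(abs(tau_null) >= abs(tau) - 1e-12)
    meth <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    meth <- "asymptotic"
  }
  new_test_result("tau-b", tau, z, min(p, 1), meth, n)
}

#' Kolmogorov-Smirnov normality screen with estimated parameters
#'
#' Lilliefors-type test: the KS distance `D` is computed against a normal
#' with the sample mean and SD, and because those parameters are
#' estimated, the null distribution of `D` is calibrated by Monte-Carlo
#' simulation rather than the standard KS tables.
#'
#' @param x Sample, n >= 4, nonzero variance.
#' @param n_mc Number of Monte-Carlo null replicates.
#' @param seed Seed for the null simulation.
#' @return An `mt_test_result` with `statistic` = D.
#' @export
ks_normality <- function(x, n_mc = 2000, seed = 1) {
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (sd(x) == 0) stop("zero variance")
  lillie_d <- function(v) {
    p <- stats::pnorm(sort(v), mean(v), sd(v))
    i <- seq_len(length(v))
    max(i / length(v) - p, p - (i - 1) / length(v))
  }
  d_obs <- lillie_d(x)
  set.seed(seed)
  d_null <- replicate(n_mc, lillie_d(rnorm(n)))
  p <- (1 + sum(d_null >= d_obs)) / (n_mc + 1)
  new_test_result("D", d_obs, NA_real_, p, "monte-carlo", n)
}

#' Cohort inference on paired pre/post exchange rates
#'
#' Runs the paired Wilcoxon signed-rank test per metabolite, counts
#' subjects whose rate increased, and (when ages are supplied) correlates
#' age with the rate change via Kendall's tau-b.
#'
#' @param results Data frame with columns `subject_id`, `session`
#'   (`"pre"`/`"post"`), `kf_pi` and optionally `kf_pcr`.
#' @param ages Optional named vector of ages (names = subject ids).
#' @return A list of class `cohort_report`: per-metabolite test results,
#'   a per-subject change table, the increased-rate count, and the age
#'   correlation (if computed). Subjects missing either session are
#'   excluded with a warning; an all-zero-change cohort is reported as
#'   "no change" rather than an error.
#' @export
run_cohort_analysis <- function(results, ages = NULL) {
  wide <- merge(results[results$session == "pre", ],
                results[results$session == "post", ],
                by = "subject_id", suffixes = c("_pre", "_post"))
  dropped <- setdiff(unique(results$subject_id), wide$subject_id)
  if (length(dropped) > 0)
    warning("excluding unpaired subject(s): ",
            paste(dropped, collapse = ", "))
  if (nrow(wide) < 2) stop("need at least 2 complete pre/post pairs")
  metabolites <- intersect(c("kf_pi", "kf_pcr"), names(results))
  tests <- list()
  for (m in metabolites) {
    pre <- wide[[paste0(m, "_pre")]]
    post <- wide[[paste0(m, "_post")]]
    tests[[m]] <- tryCatch(wilcoxon_signed_rank(pre, post),
                           error = function(e)
                             list(statistic_name = "W+", statistic = NA_real_,
                                  z = NA_real_, p_two_tailed = NA_real_,
                                  method = "none", n_effective = 0L,
                                  note = "no change between sessions"))
  }
  delta <- wide$kf_pi_post - wide$kf_pi_pre
  change_table <- data.frame(subject_id = wide$subject_id,
                             kf_pre = wide$kf_pi_pre,
                             kf_post = wide$kf_pi_post,
                             delta = delta)
  age_test <- NULL
  if (!is.null(ages)) {
    a <- ages[wide$subject_id]
    if (anyNA(a)) warning("ages missing for some subjects; skipping tau-b")
    else age_test <- kendall_tau_b(as.numeric(a), delta)
  }
  structure(list(
    tests = tests,
    change_table = change_table,
    n_pairs = nrow(wide),
    n_increased = sum(delta > 0),
    age_correlation = age_test
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d pairs; rate increased in %d\n",
              x$n_pairs, x$n_increased))
  for (m in names(x$tests)) {
    cat(" ", m, ": ")
    t <- x$tests[[m]]
    if (inherits(t, "mt_test_result")) print(t)
    else cat(t$note, "\n")
  }
  if (!is.null(x$age_correlation)) {
    cat("  age vs delta-k: ")
    print(x$age_correlation)
  }
  invisible(x)
}
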
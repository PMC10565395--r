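#' Map detection times to circular angles
#'
#' Detection instants are wrapped onto the 24 h clock: the fractional local
#' hour of day times 15 degrees, giving angles in `[0, 360)`.
#'
#' @param det A [detection_table()] (or `POSIXct` vector with `config`).
#' @param config A [study_config()]; taken from `det` when omitted.
#' @return Numeric vector of angles in degrees.
#' @export
hour_angles <- function(det, config = NULL) {
  if (inherits(det, "detection_table")) {
    config <- det_config(det)
    time <- det$timestamp
  } else time <- det
  local_hour_frac(time, config) * 15
}

#' Rao spacing statistic
#'
#' For sorted angles with successive arc gaps `T_i` (including the
#' wrap-around gap), `U = 0.5 * sum(|T_i - lambda|)` with `lambda = 360/n`.
#' U is 0 for perfectly equally spaced angles and grows as the sample
#' clusters.
#'
#' @param angles Angles in degrees.
#' @return The U statistic (degrees).
#' @export
rao_spacing_u <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("need at least two angles")
  s <- sort(angles %% 360)
  gaps <- diff(c(s, s[1] + 360))
  0.5 * sum(abs(gaps - 360 / n))
}

#' Rao spacing test of circular uniformity
#'
#' Tests whether angles are uniformly distributed on the circle. The
#' p-value is computed by Monte Carlo: the share of `n_mc` uniform samples
#' of the same size whose U statistic is at least the observed one. This
#' avoids the coarse published critical-value tables and gives a
#' reproducible p-value under a fixed seed.
#'
#' @param angles Angles in degrees; at least 4.
#' @param n_mc Number of Monte-Carlo replicates (default 10000).
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @return An object of class `htest` with the U statistic and p-value.
#' @export
rao_spacing_test <- function(angles, n_mc = 10000, seed = NULL) {
  n <- length(angles)
  if (n < 4) stop("Rao spacing test needs at least 4 angles")
  u <- rao_spacing_u(angles)
  if (!is.null(seed)) set.seed(seed)
  u_null <- rao_spacing_null(n, n_mc)
  p <- mean(u_null >= u)
  structure(list(statistic = c(U = u), p.value = p,
                 parameter = c(n = n, n_mc = n_mc),
                 method = "Rao's spacing test of uniformity (Monte-Carlo p-value)",
                 data.name = deparse(substitute(angles))),
            class = "htest")
}

# Monte-Carlo sample of the null distribution of U for sample size n.
rao_spacing_null <- function(n, n_mc) {
  m <- matrix(stats::runif(n_mc * n, 0, 360), nrow = n_mc)
  m <- t(apply(m, 1, sort))
  gaps <- cbind(m[, -1, drop = FALSE] - m[, -n, drop = FALSE],
                m[, 1] + 360 - m[, n])
  0.5 * rowSums(abs(gaps - 360 / n))
}

#' Rao test of homogeneity of circular samples
#'
#' Tests whether several circular samples share a common polar vector
#' (Rao 1967): a chi-square component for equality of mean directions and
#' one for equality of resultant lengths ("dispersions"), each on k-1
#' degrees of freedom, using delta-method variances of the per-sample
#' estimates; the combined statistic sums the two (2(k-1) d.f.).
#'
#' @param samples List of k >= 2 numeric vectors of angles in degrees, each
#'   with at least 2 distinct values.
#' @return List of class `rao_homogeneity_test` with per-component
#'   statistics, degrees of freedom and p-values.
#' @export
rao_homogeneity_test <- function(samples) {
  k <- length(samples)
  if (k < 2) stop("need at least two samples")
  stats_i <- lapply(samples, function(a) {
    n <- length(a)
    if (n < 2) stop("each sample needs at least 2 angles")
    th <- a * pi / 180
    cv <- cos(th); sv <- sin(th)
    C <- mean(cv); S <- mean(sv)
    r2 <- C^2 + S^2
    if (r2 < 1e-12) stop("a sample has a null resultant; mean direction undefined")
    s_cc <- mean(cv^2) - C^2
    s_ss <- mean(sv^2) - S^2
    s_cs <- mean(cv * sv) - C * S
    list(n = n, C = C, S = S,
         theta = atan2(S, C),
         R = sqrt(r2),
         var_theta = (S^2 * s_cc - 2 * C * S * s_cs + C^2 * s_ss) / (n * r2^2),
         var_R = (C^2 * s_cc + 2 * C * S * s_cs + S^2 * s_ss) / (n * r2))
  })
  theta <- vapply(stats_i, `[[`, numeric(1), "theta")
  # center angles on their circular mean so the wrap point is far from them
  Cbar <- mean(cos(theta)); Sbar <- mean(sin(theta))
  ref <- atan2(Sbar, Cbar)
  theta <- (theta - ref + pi) %% (2 * pi) - pi
  vt <- vapply(stats_i, `[[`, numeric(1), "var_theta")
  R <- vapply(stats_i, `[[`, numeric(1), "R")
  vR <- vapply(stats_i, `[[`, numeric(1), "var_R")
  vt <- pmax(vt, 1e-12); vR <- pmax(vR, 1e-12)
  wchisq <- function(x, v) {
    w <- 1 / v
    sum(x^2 * w) - sum(x * w)^2 / sum(w)
  }
  H_polar <- wchisq(theta, vt)
  H_disp <- wchisq(R, vR)
  df <- k - 1
  out <- list(
    statistic_polar = H_polar, p_polar = stats::pchisq(H_polar, df, lower.tail = FALSE),
    statistic_dispersion = H_disp,
    p_dispersion = stats::pchisq(H_disp, df, lower.tail = FALSE),
    statistic_combined = H_polar + H_disp,
    p_combined = stats::pchisq(H_polar + H_disp, 2 * df, lower.tail = FALSE),
    df = df, k = k)
  class(out) <- "rao_homogeneity_test"
  out
}

#' @export
print.rao_homogeneity_test <- function(x, ...) {
  cat("Rao test of homogeneity of circular samples (k =", x$k, ")\n")
  cat(sprintf("  mean directions: chi2 = %.3f, df = %d, p = %.4g\n",
              x$statistic_polar, x$df, x$p_polar))
  cat(sprintf("  dispersions:     chi2 = %.3f, df = %d, p = %.4g\n",
              x$statistic_dispersion, x$df, x$p_dispersion))
  cat(sprintf("  combined:        chi2 = %.3f, df = %d, p = %.4g\n",
              x$statistic_combined, 2 * x$df, x$p_combined))
  invisible(x)
}

#' Hourly detection profiles
#'
#' For each tag, the proportion of its detections falling in each integer
#' local hour (0-23). Tags with zero detections are excluded; each row sums
#' to 1.
#'
#' @param det A [detection_table()].
#' @return Numeric matrix, tags x 24 (columns named "0".."23").
#' @export
hourly_profiles <- function(det) {
  cfg <- det_config(det)
  if (!nrow(det)) return(matrix(numeric(), 0, 24,
                                dimnames = list(NULL, as.character(0:23))))
  hr <- factor(local_hour(det$timestamp, cfg), levels = 0:23)
  tab <- table(det$tag_id, hr)
  m <- unclass(tab / rowSums(tab))
  m <- matrix(as.numeric(m), nrow = nrow(tab),
              dimnames = list(rownames(tab), as.character(0:23)))
  m
}

#' Cluster hourly profiles
#'
#' Average-linkage (UPGMA) hierarchical clustering of the per-tag hourly
#' proportion vectors under Euclidean distance.
#'
#' @param profiles Matrix from [hourly_profiles()].
#' @param k Number of clusters for the cut (default 2); ignored when `h`
#'   is given.
#' @param h Cut height alternative to `k`.
#' @return List with `hclust` (the merge tree, `NULL` for a single profile)
#'   and `labels` (named integer cluster labels).
#' @export
cluster_profiles <- function(profiles, k = 2, h = NULL) {
  n <- nrow(profiles)
  if (n == 0) stop("no profiles to cluster")
  if (n == 1)
    return(list(hclust = NULL,
                labels = stats::setNames(1L, rownames(profiles))))
  hc <- stats::hclust(stats::dist(profiles), method = "average")
  labels <- if (!is.null(h)) stats::cutree(hc, h = h) else
    stats::cutree(hc, k = min(k, n))
  list(hclust = hc, labels = labels)
}
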
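#' Assemble the seasonal detection model table
#'
#' One row per tag and study day from the start of monitoring through that
#' tag's last detection day, with a 0/1 response (detected that day) and the
#' day-level covariates: calendar month, sea-surface temperature, daily tide
#' amplitude, plus sex and total length from the tag metadata.
#'
#' @param p A [build_presence()] object.
#' @param tags Tag metadata `data.frame` (`tag_id`, `sex`, `total_length`).
#' @param sst Daily SST `data.frame` (`date`, `sst_c`).
#' @param amplitude Daily amplitude `data.frame` (`day`, `amplitude`), e.g.
#'   from [daily_amplitude()].
#' @param na_action `"drop"` (default, rows with missing covariates removed
#'   with a message) or `"keep"`.
#' @return `data.frame` with columns `tag`, `day`, `detected`, `month`,
#'   `sex`, `total_length`, `sst`, `tide_amplitude`, `season`.
#' @export
build_seasonal_table <- function(p, tags, sst = NULL, amplitude = NULL,
                                 na_action = c("drop", "keep")) {
  na_action <- match.arg(na_action)
  last <- last_detected_index(p)
  rows <- lapply(seq_along(p$tags), function(i) {
    if (is.na(last[i])) return(NULL)
    d <- seq_len(last[i])
    data.frame(tag = p$tags[i], day = p$days[d],
               detected = as.integer(p$presence[i, d]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no detected tags in the presence matrix")
  tab$month <- as.integer(format(tab$day, "%m"))
  tab$season <- season_of(tab$day, p$config)
  m <- match(tab$tag, tags$tag_id)
  tab$sex <- factor(tags$sex[m], levels = c("female", "male"))
  tab$total_length <- tags$total_length[m]
  tab$sst <- if (!is.null(sst)) sst$sst_c[match(tab$day, sst$date)] else NA_real_
  tab$tide_amplitude <- if (!is.null(amplitude))
    amplitude$amplitude[match(tab$day, amplitude$day)] else NA_real_
  tab$tag <- factor(tab$tag)
  finalize_model_table(tab, na_action,
                       c("month", "sex",
                         if (!is.null(sst)) "sst",
                         if (!is.null(amplitude)) "tide_amplitude"))
}

#' Assemble the roaming model table
#'
#' One row per tag and *present* day, with a binomial (successes, failures)
#' response: receivers visited vs not visited out of the `R` active
#' receivers, joined with the per-sex detected/remaining proportions
#' (`prop_f`, `prop_m`) and the day-level covariates.
#'
#' @inheritParams build_seasonal_table
#' @param R Active receiver count (defaults to the receivers in `p`).
#' @return `data.frame` with `tag`, `day`, `visited`, `not_visited`,
#'   `prop_f`, `prop_m`, `month`, `season`, `sex`, `total_length`, `sst`,
#'   `tide_amplitude`.
#' @export
build_roaming_table <- function(p, tags, sst = NULL, amplitude = NULL,
                                R = NULL, na_action = c("drop", "keep")) {
  na_action <- match.arg(na_action)
  if (is.null(R)) R <- length(p$receivers)
  pf <- remaining_proportion(p, sex = "female", tags_meta = tags)
  pm <- remaining_proportion(p, sex = "male", tags_meta = tags)
  rows <- lapply(seq_along(p$tags), function(i) {
    d <- which(p$presence[i, ])
    if (!length(d)) return(NULL)
    data.frame(tag = p$tags[i], day = p$days[d],
               visited = as.integer(p$n_receivers[i, d]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no present days")
  tab$not_visited <- R - tab$visited
  tab$month <- as.integer(format(tab$day, "%m"))
  tab$season <- season_of(tab$day, p$config)
  m <- match(tab$tag, tags$tag_id)
  tab$sex <- factor(tags$sex[m], levels = c("female", "male"))
  tab$total_length <- tags$total_length[m]
  tab$prop_f <- pf$proportion[match(tab$day, pf$day)]
  tab$prop_m <- pm$proportion[match(tab$day, pm$day)]
  tab$sst <- if (!is.null(sst)) sst$sst_c[match(tab$day, sst$date)] else NA_real_
  tab$tide_amplitude <- if (!is.null(amplitude))
    amplitude$amplitude[match(tab$day, amplitude$day)] else NA_real_
  tab$tag <- factor(tab$tag)
  finalize_model_table(tab, na_action,
                       c("prop_f", "prop_m",
                         if (!is.null(sst)) "sst",
                         if (!is.null(amplitude)) "tide_amplitude"))
}

#' Assemble the intra-day detection model table
#'
#' One row per tag, present day and hour (24 rows per present day), with a
#' 0/1 response (any detection in that local hour) and the hourly tide
#' covariates.
#'
#' @param det A curated [detection_table()].
#' @param p A [build_presence()] object built from `det`.
#' @param tide Hourly tide covariates from [tide_covariates()].
#' @param tags Tag metadata `data.frame`.
#' @param na_action `"drop"` or `"keep"`, as in [build_seasonal_table()].
#' @return `data.frame` with `tag`, `day`, `hour`, `detected`, `season`,
#'   `sex`, `total_length`, `height`, `height_class`, `direction`,
#'   `strength`.
#' @export
build_intraday_table <- function(det, p, tide, tags,
                                 na_action = c("drop", "keep")) {
  na_action <- match.arg(na_action)
  cfg <- p$config
  rows <- lapply(seq_along(p$tags), function(i) {
    d <- which(p$presence[i, ])
    if (!length(d)) return(NULL)
    expand.grid(hour = 0:23, day_idx = d, KEEP.OUT.ATTRS = FALSE) |>
      transform(tag = p$tags[i])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no present days")
  tab$day <- p$days[tab$day_idx]
  tab$day_idx <- NULL
  # which (tag, day, hour) cells saw a detection
  dd <- local_day(det$timestamp, cfg)
  hh <- local_hour(det$timestamp, cfg)
  det_key <- unique(paste(det$tag_id, dd, hh))
  tab$detected <- as.integer(paste(tab$tag, tab$day, tab$hour) %in% det_key)
  # UTC instant of each local (day, hour) for the tide join
  utc <- as.numeric(as.POSIXct(tab$day, tz = "UTC")) + tab$hour * 3600 -
    cfg$local_utc_offset * 3600
  ti <- match(utc, as.numeric(tide$time))
  tab$height <- tide$height[ti]
  tab$height_class <- tide$height_class[ti]
  tab$direction <- tide$direction[ti]
  tab$strength <- tide$strength[ti]
  tab$season <- season_of(tab$day, cfg)
  m <- match(tab$tag, tags$tag_id)
  tab$sex <- factor(tags$sex[m], levels = c("female", "male"))
  tab$total_length <- tags$total_length[m]
  tab$tag <- factor(tab$tag)
  finalize_model_table(tab, na_action,
                       c("height", "height_class", "direction", "strength"))
}

finalize_model_table <- function(tab, na_action, check_cols) {
  check_cols <- intersect(check_cols, names(tab))
  if (na_action == "drop" && length(check_cols)) {
    bad <- Reduce(`|`, lapply(tab[check_cols], is.na))
    if (any(bad))
      message(sum(bad), " row(s) with missing covariates dropped")
    tab <- tab[!bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Fit a binomial additive model with per-tag random intercepts
#'
#' Thin wrapper around `mgcv::gam()` (binomial family, REML) that fixes the
#' conventions used throughout this package: cyclic cubic smooths for month
#' (knots at 0.5/12.5) and hour (knots at -0.5/23.5) so predictions are
#' periodic, random intercepts as ridge-penalized `s(tag, bs = "re")` terms
#' (the standard GAMM-as-GAM device), and AICc bookkeeping with the fit's
#' total effective degrees of freedom as the parameter count.
#'
#' @param table A model table from one of the `build_*_table()` functions.
#' @param formula Model formula; `s(month, bs = "cc")`, `s(hour,
#'   bs = "cc")`, `s(tag, bs = "re")` etc.
#' @param knots Optional knots list; cyclic knots for `month`/`hour` are
#'   added automatically when those smooths appear.
#' @param ... Passed to `mgcv::gam()`.
#' @return A `tg_gam`: list with the fitted `model`, `formula`, `aic`,
#'   `aicc`, `k` (effective parameters), `n`, `dev_expl`, `converged`.
#' @export
fit_binomial_gam <- function(table, formula, knots = NULL, ...) {
  fstr <- paste(deparse(formula), collapse = " ")
  if (is.null(knots)) knots <- list()
  if (grepl("s\\(month", fstr) && is.null(knots$month) &&
      grepl("bs = \"cc\"", fstr))
    knots$month <- c(0.5, 12.5)
  if (grepl("s\\(hour", fstr) && is.null(knots$hour))
    knots$hour <- c(-0.5, 23.5)
  if (!length(knots)) knots <- NULL
  model <- try(mgcv::gam(formula, family = stats::binomial(),
                         data = table, method = "REML", knots = knots, ...),
               silent = TRUE)
  if (inherits(model, "try-error"))
    return(structure(list(model = NULL, formula = formula, aic = NA_real_,
                          aicc = NA_real_, k = NA_real_, n = nrow(table),
                          dev_expl = NA_real_, converged = FALSE,
                          error = attr(model, "condition")$message),
                     class = "tg_gam"))
  k <- as.numeric(attr(stats::logLik(model), "df"))
  n <- stats::nobs(model)
  aic <- stats::AIC(model)
  structure(list(model = model, formula = formula,
                 aic = aic, aicc = aicc(aic, k, n), k = k, n = n,
                 dev_expl = summary(model)$dev.expl,
                 converged = isTRUE(model$converged)),
            class = "tg_gam")
}

#' @export
print.tg_gam <- function(x, ...) {
  cat("Binomial GAM:", paste(deparse(x$formula), collapse = ""), "\n")
  if (!x$converged) { cat("  ** did not converge **\n"); return(invisible(x)) }
  cat(sprintf("  n = %d, k(eff) = %.1f, AIC = %.1f, AICc = %.1f, dev.expl = %.1f%%\n",
              x$n, x$k, x$aic, x$aicc, 100 * x$dev_expl))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`; infinite when `n <= k + 1`.
#'
#' @param aic AIC value.
#' @param k Effective number of parameters.
#' @param n Sample size.
#' @return AICc.
#' @export
aicc <- function(aic, k, n) {
  ifelse(n - k - 1 <= 0, Inf, aic + 2 * k * (k + 1) / (n - k - 1))
}

#' Rank fitted models by AICc
#'
#' @param fits Named list of [fit_binomial_gam()] results.
#' @return `data.frame` sorted by AICc with `model`, `k`, `aic`, `aicc`,
#'   `delta_aicc`, `dev_expl`, `converged`; non-converged fits are excluded
#'   from the ranking with a warning and listed at the bottom.
#' @export
aicc_rank <- function(fits) {
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("m", seq_along(fits))
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    dev_expl = vapply(fits, `[[`, numeric(1), "dev_expl"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  if (any(!tab$converged))
    warning("excluding non-converged fit(s): ",
            paste(tab$model[!tab$converged], collapse = ", "))
  ok <- tab[tab$converged, , drop = FALSE]
  ok <- ok[order(ok$aicc), , drop = FALSE]
  ok$delta_aicc <- ok$aicc - ok$aicc[1]
  bad <- tab[!tab$converged, , drop = FALSE]
  if (nrow(bad)) bad$delta_aicc <- NA_real_
  out <- rbind(ok, bad)
  rownames(out) <- NULL
  out[c("model", "k", "aic", "aicc", "delta_aicc", "dev_expl", "converged")]
}

#' Candidate model sets
#'
#' The nesting pattern used for model selection: a global model, drop-one
#' fixed-term variants, and random-effect variants (per-tag intercept,
#' sex-stratified tag intercept, none). `tag_sex` columns (the tag-within-
#' sex ridge) are added to the table by [fit_candidates()] when needed.
#'
#' @param kind `"seasonal"`, `"roaming"` or `"intraday"`.
#' @return Named list of formulas.
#' @export
candidate_models <- function(kind = c("seasonal", "roaming", "intraday")) {
  kind <- match.arg(kind)
  f <- switch(kind,
    seasonal = list(
      global_tagsex = detected ~ sex + s(total_length, k = 4) +
        s(month, bs = "cc", k = 6) + s(month, by = sex, bs = "cc", k = 6) +
        s(sst, k = 5) + s(tide_amplitude, k = 5) + s(tag_sex, bs = "re"),
      global_tag = detected ~ sex + s(total_length, k = 4) +
        s(month, bs = "cc", k = 6) + s(month, by = sex, bs = "cc", k = 6) +
        s(sst, k = 5) + s(tide_amplitude, k = 5) + s(tag, bs = "re"),
      drop_tl_tag = detected ~ sex +
        s(month, bs = "cc", k = 6) + s(month, by = sex, bs = "cc", k = 6) +
        s(sst, k = 5) + s(tide_amplitude, k = 5) + s(tag, bs = "re"),
      drop_monthsex_tag = detected ~ sex + s(total_length, k = 4) +
        s(month, bs = "cc", k = 6) +
        s(sst, k = 5) + s(tide_amplitude, k = 5) + s(tag, bs = "re"),
      global_nore = detected ~ sex + s(total_length, k = 4) +
        s(month, bs = "cc", k = 6) + s(month, by = sex, bs = "cc", k = 6) +
        s(sst, k = 5) + s(tide_amplitude, k = 5)),
    roaming = list(
      global_tag = cbind(visited, not_visited) ~ sex + s(total_length, k = 4) +
        season + s(prop_f, k = 5) + s(prop_f, by = sex, k = 5) +
        s(prop_m, k = 5) + s(prop_m, by = sex, k = 5) +
        s(sst, k = 5) + s(tide_amplitude, k = 5) + s(tag, bs = "re"),
      reduced_tag = cbind(visited, not_visited) ~ sex +
        s(prop_f, k = 5) + s(prop_f, by = sex, k = 5) +
        s(prop_m, k = 5) + s(prop_m, by = sex, k = 5) +
        s(sst, k = 5) + s(tag, bs = "re"),
      global_tagsex = cbind(visited, not_visited) ~ sex + s(total_length, k = 4) +
        season + s(prop_f, k = 5) + s(prop_f, by = sex, k = 5) +
        s(prop_m, k = 5) + s(prop_m, by = sex, k = 5) +
        s(sst, k = 5) + s(tide_amplitude, k = 5) + s(tag_sex, bs = "re"),
      global_nore = cbind(visited, not_visited) ~ sex + s(total_length, k = 4) +
        season + s(prop_f, k = 5) + s(prop_f, by = sex, k = 5) +
        s(prop_m, k = 5) + s(prop_m, by = sex, k = 5) +
        s(sst, k = 5) + s(tide_amplitude, k = 5),
      no_interactions_tag = cbind(visited, not_visited) ~ sex +
        s(total_length, k = 4) + season + s(prop_f, k = 5) + s(prop_m, k = 5) +
        s(sst, k = 5) + s(tide_amplitude, k = 5) + s(tag, bs = "re")),
    intraday = list(
      global_tag = detected ~ sex + s(hour, bs = "cc", k = 6) +
        s(hour, by = sex, bs = "cc", k = 6) + height_class +
        height_class:sex + direction + direction:sex + s(tag, bs = "re"),
      global_tl_tag = detected ~ sex + s(total_length, k = 4) +
        s(hour, bs = "cc", k = 6) + s(hour, by = sex, bs = "cc", k = 6) +
        height_class + height_class:sex + direction + direction:sex +
        s(tag, bs = "re"),
      global_nore = detected ~ sex + s(hour, bs = "cc", k = 6) +
        s(hour, by = sex, bs = "cc", k = 6) + height_class +
        height_class:sex + direction + direction:sex,
      no_interactions_tag = detected ~ sex + s(hour, bs = "cc", k = 6) +
        height_class + direction + strength + s(tag, bs = "re"),
      main_effects = detected ~ sex + s(hour, bs = "cc", k = 6) +
        height_class + direction))
  f
}

#' Fit a candidate set and rank it
#'
#' @param table A model table.
#' @param formulas Named list of formulas (default: [candidate_models()]
#'   for `kind`).
#' @param kind Passed to [candidate_models()] when `formulas` is `NULL`.
#' @return List with `fits` (named `tg_gam` list) and `ranking`
#'   (from [aicc_rank()]).
#' @export
fit_candidates <- function(table, formulas = NULL,
                           kind = c("seasonal", "roaming", "intraday")) {
  if (is.null(formulas)) formulas <- candidate_models(match.arg(kind))
  if (is.null(table$tag_sex))
    table$tag_sex <- interaction(table$tag, table$sex, drop = TRUE)
  fits <- lapply(formulas, function(f) fit_binomial_gam(table, f))
  list(fits = fits, ranking = aicc_rank(fits))
}

#' Evaluate a fitted smooth on a grid
#'
#' Returns the contribution of one smooth term (centered, link scale) over
#' a covariate grid, all other covariates held at reference values.
#'
#' @param fit A `tg_gam`.
#' @param term Smooth label as reported by mgcv, e.g. `"s(month)"`.
#' @param newdata `data.frame` covering every model covariate.
#' @return Numeric vector of the term's contribution for each row.
#' @export
evaluate_smooth <- function(fit, term, newdata) {
  stopifnot(inherits(fit, "tg_gam"), !is.null(fit$model))
  tm <- stats::predict(fit$model, newdata = newdata, type = "terms")
  if (!term %in% colnames(tm))
    stop("term '", term, "' not in the model; available: ",
         paste(colnames(tm), collapse = ", "))
  as.numeric(tm[, term])
}
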
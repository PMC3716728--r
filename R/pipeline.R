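#' Run the full inequality analysis for a set of population groups
#'
#' For every group: fit the relational model to its (5q0, 45q15) targets —
#' estimating 45q15 from the national rate and under-five ratios when
#' `use_estimator` is `TRUE` — build the abridged life table, derive the
#' death distribution, and compute life expectancy, the Gini health index
#' and ALI. Across groups (when there are at least two): the concentration
#' index over life expectancies in socioeconomic rank order and the absolute
#' difference between the best- and worst-off groups. A national total row
#' is computed either by pooling the share-weighted group death
#' distributions (default) or by refitting the relational model to the
#' share-weighted national (5q0, 45q15).
#'
#' @param cfg A list (or path to a YAML file) with elements:
#'   * `groups`: group data frame (or CSV path) with `name`, `rank`,
#'     `pop_share`, `q5`, and `q45_15` unless `use_estimator` is `TRUE`;
#'   * `national_q45_15`: national adult mortality (needed by the estimator
#'     and the `refit` national mode);
#'   * `standard`: a `standard_schedule`, a CSV path, or `"builtin"`;
#'   * `use_estimator`: logical (default `TRUE` iff `q45_15` is absent);
#'   * `v`: Gini inequality-aversion parameter (default 2);
#'   * `ax_rule`: separation-factor rule (default demographic);
#'   * `national`: `"pooled"` (default) or `"refit"`.
#' @return An object of class `inequality_report`: list with `groups` (name,
#'   rank, pop_share, q5, q45_15, le, gini_h, ali), `between` (ci,
#'   abs_diff; `NULL` with fewer than two groups), `national` (le, gini_h,
#'   ali), `tables` (fitted life tables) and `meta` (standard label, ax
#'   rule, v, estimator and national modes).
#' @export
run_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  groups <- cfg$groups
  if (is.character(groups)) groups <- read_groups_csv(groups)
  validate_groups(groups)

  std <- cfg$standard
  if (is.null(std) || identical(std, "builtin")) std <- builtin_standard()
  if (is.character(std)) std <- read_standard_csv(std)
  ax <- if (is.null(cfg$ax_rule)) ax_rule() else cfg$ax_rule
  v <- if (is.null(cfg$v)) 2 else cfg$v
  use_est <- if (is.null(cfg$use_estimator)) is.null(groups$q45_15) else
    cfg$use_estimator
  national_mode <- if (is.null(cfg$national)) "pooled" else cfg$national

  stage <- function(what, group, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed for group '%s': %s",
                   what, group, conditionMessage(e)), call. = FALSE)
    })
  }

  if (use_est) {
    if (is.null(cfg$national_q45_15)) {
      stop("the adult-mortality estimator needs cfg$national_q45_15")
    }
    groups <- stage("estimate 45q15", "all",
                    estimate_group_adult_mortality(groups,
                                                   cfg$national_q45_15))
  } else if (is.null(groups$q45_15)) {
    stop("groups need a q45_15 column when use_estimator is FALSE")
  }

  k <- nrow(groups)
  tables <- vector("list", k)
  dists <- vector("list", k)
  out <- groups[, c("name", "rank", "pop_share", "q5", "q45_15")]
  out$le <- out$gini_h <- out$ali <- NA_real_
  for (i in seq_len(k)) {
    lt <- stage("life table fit", groups$name[i],
                model_group_life_table(
                  fit_targets(groups$q5[i], groups$q45_15[i]), std,
                  ax_rule = ax))
    dd <- derive_death_distribution(lt)
    tables[[i]] <- lt
    dists[[i]] <- dd
    out$le[i] <- life_expectancy(lt)
    out$gini_h[i] <- stage("gini", groups$name[i], gini_h(dd, v = v))
    out$ali[i] <- ali(out$le[i], out$gini_h[i])
  }

  between <- NULL
  if (k >= 2) {
    between <- list(
      ci = concentration_index(out$le, f = out$pop_share, rank = out$rank),
      abs_diff = absolute_difference(out$le[which.max(out$rank)],
                                     out$le[which.min(out$rank)]))
  }

  national <- if (national_mode == "refit") {
    q5_nat <- sum(out$pop_share * out$q5)
    q45_nat <- if (!is.null(cfg$national_q45_15)) cfg$national_q45_15 else
      sum(out$pop_share * out$q45_15)
    lt <- model_group_life_table(fit_targets(q5_nat, q45_nat), std,
                                 ax_rule = ax)
    dd <- derive_death_distribution(lt)
    g <- gini_h(dd, v = v)
    list(le = life_expectancy(lt), gini_h = g,
         ali = ali(life_expectancy(lt), g), mode = "refit")
  } else {
    dd <- pool_death_distributions(dists, out$pop_share)
    mu <- sum(dd$f * dd$h)
    g <- gini_h(dd, v = v)
    list(le = mu, gini_h = g, ali = ali(mu, g), mode = "pooled")
  }

  structure(
    list(groups = out, between = between, national = national,
         tables = tables,
         meta = list(standard = std$label,
                     ax_rule = if (is.numeric(ax)) "explicit" else ax$name,
                     corrections = any(std$gamma != 0) || any(std$theta != 0),
                     v = v, use_estimator = use_est,
                     national = national_mode)),
    class = "inequality_report"
  )
}

#' Pool several death distributions with population weights
#'
#' Interval-wise pooling on a shared grid: pooled shares are the weighted
#' mean of group shares; each interval's mean age at death is the
#' deaths-weighted mean of the group values, so the pooled mean age at death
#' equals the share-weighted mean of group life expectancies exactly.
#'
#' @param dists List of `death_distribution`s on the same grid.
#' @param weights Population shares summing to 1.
#' @return A pooled `death_distribution`.
#' @export
pool_death_distributions <- function(dists, weights) {
  stopifnot(length(dists) == length(weights),
            abs(sum(weights) - 1) < 1e-9)
  fmat <- vapply(dists, `[[`, numeric(length(dists[[1]]$f)), "f")
  hmat <- vapply(dists, `[[`, numeric(length(dists[[1]]$h)), "h")
  f <- drop(fmat %*% weights)
  fh <- drop((fmat * hmat) %*% weights)
  h <- ifelse(f > 0, fh / f, hmat[, 1])
  structure(list(h = h, f = f), class = "death_distribution")
}

#' @export
print.inequality_report <- function(x, ...) {
  cat("Inequality report (standard:", x$meta$standard, "| ax:",
      x$meta$ax_rule, "| v =", x$meta$v, ")\n")
  print(render_tables(x)$table, row.names = FALSE)
  invisible(x)
}

#' Render an inequality report as a publication-style table
#'
#' Rounds to the conventional reporting precision: life expectancy, ALI and
#' absolute difference at 1 decimal (years), Gini at 2 decimals, CI at 3
#' decimals; between-group cells are `-` on the national row and repeated
#' only once per grouping. Full precision is retained in the report object
#' itself.
#'
#' @param report An `inequality_report`.
#' @return A list with `table` (character data frame mirroring the printed
#'   layout) and `text` (formatted lines).
#' @export
render_tables <- function(report) {
  g <- report$groups
  k <- nrow(g)
  ci_col <- rep("", k)
  ad_col <- rep("", k)
  if (!is.null(report$between)) {
    mid <- ceiling(k / 2)
    ci_col[mid] <- sprintf("%.3f", report$between$ci)
    ad_col[mid] <- sprintf("%.1f", report$between$abs_diff)
  }
  tab <- data.frame(
    group = g$name,
    LE = sprintf("%.1f", g$le),
    Gini_H = sprintf("%.2f", g$gini_h),
    ALI = sprintf("%.1f", g$ali),
    CI = ci_col,
    Abs.diff = ad_col,
    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(
    group = "Total",
    LE = sprintf("%.1f", report$national$le),
    Gini_H = sprintf("%.2f", report$national$gini_h),
    ALI = sprintf("%.1f", report$national$ali),
    CI = "-", Abs.diff = "-", stringsAsFactors = FALSE))
  widths <- vapply(names(tab), function(nm) {
    max(nchar(nm), max(nchar(tab[[nm]])))
  }, integer(1))
  fmt_row <- function(cells) {
    paste(mapply(formatC, cells, width = widths), collapse = "  ")
  }
  text <- c(fmt_row(names(tab)),
            apply(tab, 1, fmt_row))
  list(table = tab, text = unname(text))
}

#' Write an inequality report to disk
#'
#' Serializes the report as `report.json` plus CSVs mirroring the published
#' table layout (`groups.csv` with full-precision values, `table.csv` with
#' the rounded rendering). Writing is all-or-nothing: files are staged in a
#' temporary directory and moved into place only on success.
#'
#' @param report An `inequality_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stage <- tempfile("report-stage-")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  core <- list(
    groups = report$groups,
    between = report$between,
    national = report$national,
    meta = report$meta)
  jsonlite::write_json(core, file.path(stage, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$groups, file.path(stage, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(render_tables(report)$table, file.path(stage, "table.csv"),
                   row.names = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(stage)) {
    file.copy(file.path(stage, f), file.path(dir, f), overwrite = TRUE)
  }
  invisible(dir)
}

#' Export a death distribution as deaths per 1000 births by age group
#'
#' Scales the radix-1 deaths column to deaths per `per` births, the usual
#' scale for plotting mortality distributions by age group.
#'
#' @param lt An abridged life table.
#' @param per Radix for the output scale (default 1000).
#' @return A data frame with `age` (interval lower bound), `width` and
#'   `deaths` (per `per` births).
#' @export
death_distribution_export <- function(lt, per = 1000) {
  stopifnot(inherits(lt, "abridged_life_table"))
  data.frame(age = lt$grid$lower, width = lt$grid$width,
             deaths = lt$dx * per)
}
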
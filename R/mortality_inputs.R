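#' Group specifications
#'
#' Population groups are held in a plain data frame with columns `name`,
#' `rank` (socioeconomic order, 1 = worst-off), `pop_share` (fractions
#' summing to 1) and `q5` (under-five mortality 5q0). The helper
#' [derive_u5_ratios()] adds `u5_ratio`, each group's 5q0 relative to the
#' best-off (highest-rank) reference group.
#'
#' @param name Group labels.
#' @param rank Socioeconomic order, 1 = worst-off.
#' @param pop_share Population fractions summing to 1.
#' @param q5 Under-five mortality per group (may be `NA` when only ratios
#'   are supplied).
#' @param u5_ratio Optional pre-computed ratios of each group's 5q0 to the
#'   reference group's.
#' @return A validated `data.frame` of groups.
#' @export
group_spec <- function(name, rank, pop_share, q5 = NA_real_, u5_ratio = NULL) {
  df <- data.frame(name = as.character(name), rank = as.integer(rank),
                   pop_share = as.numeric(pop_share), q5 = as.numeric(q5),
                   stringsAsFactors = FALSE)
  if (!is.null(u5_ratio)) df$u5_ratio <- as.numeric(u5_ratio)
  validate_groups(df)
  df
}

validate_groups <- function(groups) {
  stopifnot(is.data.frame(groups))
  needed <- c("name", "rank", "pop_share")
  if (!all(needed %in% names(groups))) {
    stop("groups need columns ", paste(needed, collapse = ", "))
  }
  if (abs(sum(groups$pop_share) - 1) > 1e-9) {
    stop("population shares must sum to 1, got ", sum(groups$pop_share))
  }
  if (any(groups$pop_share <= 0)) stop("population shares must be positive")
  if (anyDuplicated(groups$rank)) stop("group ranks must be distinct")
  if (!is.null(groups$u5_ratio) && any(groups$u5_ratio <= 0, na.rm = TRUE)) {
    stop("under-five mortality ratios must be positive")
  }
  invisible(groups)
}

#' Under-five mortality ratios relative to the best-off group
#'
#' The reference group is the one with the highest `rank` (best-off, e.g.
#' urban residents or the top wealth quintile); its ratio is 1 by definition
#' and every other group's ratio is `q5_group / q5_reference`.
#'
#' @param groups A group data frame with a `q5` column.
#' @return The groups with a `u5_ratio` column added (or recomputed).
#' @export
derive_u5_ratios <- function(groups) {
  validate_groups(groups)
  if (any(!is.finite(groups$q5) | groups$q5 <= 0)) {
    stop("all groups need a positive q5 to derive ratios")
  }
  ref <- which.max(groups$rank)
  groups$u5_ratio <- groups$q5 / groups$q5[ref]
  groups
}

#' Correction factor x for group adult-mortality estimation
#'
#' `x = 1 / sum(u5_ratio_i * pop_share_i)`. By construction the
#' population-share-weighted mean of the adjusted ratios `u5_ratio_i * x`
#' equals 1, so the group adult-mortality estimates of
#' [group_adult_mortality()] average back (share-weighted) to the national
#' rate.
#'
#' @param groups A group data frame with `u5_ratio` and `pop_share` columns
#'   (see [derive_u5_ratios()]).
#' @return The scalar correction factor.
#' @examples
#' g <- group_spec(c("rural", "urban"), rank = c(1, 2),
#'                 pop_share = c(0.832, 0.168), u5_ratio = c(1.373, 1))
#' correction_factor(g)  # 0.763
#' @export
correction_factor <- function(groups) {
  validate_groups(groups)
  if (is.null(groups$u5_ratio)) {
    stop("groups need a u5_ratio column; see derive_u5_ratios()")
  }
  1 / sum(groups$u5_ratio * groups$pop_share)
}

#' Estimate a group's adult mortality from the national rate
#'
#' Scales the national adult mortality by the group's under-five mortality
#' ratio and the normalization factor `x` of [correction_factor()]:
#' `45q15_group = 45q15_national * u5_ratio * x`. Because `x` normalizes the
#' share-weighted ratios to mean 1, the estimates preserve the national rate
#' on average while importing the *tendency* of the under-five gradient into
#' adult ages.
#'
#' @param national National adult mortality 45q15 (probability).
#' @param group A single-row group data frame (or list) with `u5_ratio` and
#'   `name`, or a bare numeric ratio.
#' @param x Correction factor from [correction_factor()].
#' @return The group's estimated 45q15.
#' @examples
#' group_adult_mortality(0.2739, 1.373, 0.763)  # 0.287
#' @export
group_adult_mortality <- function(national, group, x) {
  if (is.numeric(group)) {
    ratio <- group
    name <- "group"
  } else {
    ratio <- group$u5_ratio
    name <- group$name
  }
  stopifnot(length(ratio) == 1, length(national) == 1, length(x) == 1)
  if (national <= 0 || ratio <= 0 || x <= 0) {
    stop("all factors must be positive")
  }
  q <- national * ratio * x
  if (q >= 1) {
    stop("estimated 45q15 for ", name, " is ", format(q),
         ", outside (0, 1)")
  }
  q
}

#' Estimate adult mortality for every group
#'
#' Convenience wrapper: derives under-five ratios if needed, computes the
#' correction factor, and applies [group_adult_mortality()] per group.
#'
#' @param groups Group data frame with `q5` (or `u5_ratio`).
#' @param national National adult mortality 45q15.
#' @return The groups with columns `u5_ratio` and `q45_15` filled in;
#'   the correction factor is attached as attribute `"x"`.
#' @export
estimate_group_adult_mortality <- function(groups, national) {
  if (is.null(groups$u5_ratio)) groups <- derive_u5_ratios(groups)
  x <- correction_factor(groups)
  groups$q45_15 <- vapply(
    seq_len(nrow(groups)),
    function(i) group_adult_mortality(national, groups[i, ], x),
    numeric(1))
  attr(groups, "x") <- x
  groups
}

#' Combine male and female mortality schedules
#'
#' Sex-specific conditional death probabilities on a shared grid are combined
#' on the central-death-rate scale with a constant male population weight:
#' each `qx` is converted to a rate with the mid-interval approximation
#' `m = q / (n * (1 - q/2))`, rates are mixed as
#' `m = s * m_male + (1 - s) * m_female`, and the mix is converted back with
#' the same approximation. The open-ended last interval stays at probability
#' 1.
#'
#' @param qx_male,qx_female Equal-length death-probability vectors.
#' @param male_share Fraction of the population that is male, in (0, 1)
#'   (the boundary values return the single-sex schedule exactly).
#' @param grid The shared [age_grid()].
#' @return Combined `qx` vector.
#' @export
combine_sexes <- function(qx_male, qx_female, male_share, grid) {
  if (length(qx_male) != length(qx_female) ||
      length(qx_male) != grid$k) {
    stop("schedules and grid must have matching lengths")
  }
  if (male_share < 0 || male_share > 1) {
    stop("male_share must lie in [0, 1], got ", male_share)
  }
  if (male_share == 0) return(as.numeric(qx_female))
  if (male_share == 1) return(as.numeric(qx_male))
  n <- grid$width
  closed <- is.finite(n)
  to_m <- function(q) q / (n[closed] * (1 - q / 2))
  m <- male_share * to_m(qx_male[closed]) +
    (1 - male_share) * to_m(qx_female[closed])
  q <- n[closed] * m / (1 + n[closed] * m / 2)
  out <- numeric(grid$k)
  out[closed] <- pmin(q, 1)
  out[!closed] <- 1
  out
}

#' Read group inputs from CSV
#'
#' Expected columns: `name`, `rank`, `pop_share`, `q5` (and optionally
#' `u5_ratio`, `q45_15`).
#'
#' @param path CSV file path.
#' @return A validated group data frame.
#' @export
read_groups_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_groups(df)
  df
}
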
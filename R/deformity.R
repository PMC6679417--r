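#' Apply the field-of-view stopping rule to one deformity scan
#'
#' Fields of view are counted in order until the cumulative cell count
#' reaches the target; the final field is always counted in full, so the
#' total may overshoot the target but a partial field is never counted.
#' Indiscernible aggregations (`excluded` column) are tallied separately and
#' never enter any denominator.
#'
#' @param fields Tibble of ordered fields of view with columns `field_idx`,
#'   `normal`, `kink`, `coil`, `short`, `tailless` and optionally
#'   `excluded`. One scan (one male) at a time.
#' @param target Stopping target, cells (default 100).
#' @return A one-row tibble: per-category totals, `total_counted`,
#'   `n_fields_counted`, `excluded_total`, `deformed` and
#'   `proportion_deformed = deformed / total_counted`.
#' @export
#' @examples
#' fields <- tibble::tibble(
#'   field_idx = 1:4, normal = c(20, 30, 18, 15), kink = c(5, 5, 4, 3),
#'   coil = c(3, 3, 2, 1), short = c(1, 1, 1, 1), tailless = c(1, 1, 0, 0)
#' )
#' count_scan(fields, target = 100)
count_scan <- function(fields, target = 100) {
  cats <- DEFORMITY_CATEGORIES
  check_columns(fields, c("field_idx", cats))
  if (!is.numeric(target) || length(target) != 1 || target < 1) {
    abort("`target` must be a single count >= 1.")
  }
  if (nrow(fields) == 0) {
    abort("Scan has no fields of view.")
  }
  counts <- as.matrix(fields[, cats])
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Field counts must be non-negative integers.")
  }
  fields <- arrange(as_tibble(fields), .data$field_idx)
  per_field <- rowSums(as.matrix(fields[, cats]))
  cum <- cumsum(per_field)
  if (cum[length(cum)] < target) {
    abort(sprintf(
      "Scan exhausted below target: %d cells over %d fields, %d short of %d.",
      cum[length(cum)], nrow(fields), target - cum[length(cum)], target
    ))
  }
  k <- which(cum >= target)[1]
  counted <- fields[seq_len(k), , drop = FALSE]
  totals <- colSums(as.matrix(counted[, cats]))
  excluded_total <- if ("excluded" %in% names(counted)) {
    sum(counted$excluded)
  } else {
    0L
  }
  total <- sum(totals)
  tibble(
    normal = totals[["normal"]], kink = totals[["kink"]],
    coil = totals[["coil"]], short = totals[["short"]],
    tailless = totals[["tailless"]],
    total_counted = total,
    n_fields_counted = k,
    excluded_total = as.integer(excluded_total),
    deformed = total - totals[["normal"]],
    proportion_deformed = (total - totals[["normal"]]) / total
  )
}

#' Per-male deformity counts for a whole study
#'
#' Applies [count_scan()] male by male to a study's field-scan table.
#'
#' @param fields Tibble of fields of view with a `male_id` column.
#' @param target Stopping target per male (default 100).
#' @param males Optional males tibble supplying a `group` column.
#' @return One row per male with the [count_scan()] summary columns.
#' @export
deformity_counts <- function(fields, target = 100, males = NULL) {
  check_columns(fields, c("male_id", "field_idx", DEFORMITY_CATEGORIES))
  parts <- split(select(as_tibble(fields), -"male_id"),
                 factor(fields$male_id, levels = unique(fields$male_id)))
  out <- bind_rows(lapply(parts, count_scan, target = target),
                   .id = "male_id")
  if (!is.null(males) && "group" %in% names(males)) {
    out <- out %>%
      left_join(select(males, "male_id", "group"), by = "male_id") %>%
      select("male_id", "group", dplyr::everything())
  }
  out
}

#' Tabulate deformity proportions by acclimation group
#'
#' Summarises per-male deformity counts into per-group mean category
#' proportions, alongside the per-male raw proportions.
#'
#' @param counts Per-male counts from [deformity_counts()], with a `group`
#'   column.
#' @return A list of two tibbles: `by_male` (per-male category proportions)
#'   and `by_group` (per-group means of those proportions, with
#'   `n_males`).
#' @export
tabulate_deformity <- function(counts) {
  cats <- DEFORMITY_CATEGORIES
  check_columns(counts, c("male_id", "group", cats, "total_counted",
                          "proportion_deformed"))
  if (nrow(counts) == 0) {
    abort("No deformity counts supplied.")
  }
  by_male <- counts %>%
    mutate(across(all_of(cats), ~ .x / .data$total_counted,
                  .names = "prop_{.col}")) %>%
    select("male_id", "group", "total_counted",
           dplyr::starts_with("prop_"), "proportion_deformed")
  by_group <- by_male %>%
    group_by(.data$group) %>%
    summarise(
      n_males = dplyr::n(),
      across(c(dplyr::starts_with("prop_"), "proportion_deformed"), mean),
      .groups = "drop"
    )
  list(by_male = by_male, by_group = by_group)
}
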
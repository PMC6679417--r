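#' Run the full analysis over a study
#'
#' Chains the pipeline stages in order - per-cell morphometric derivation,
#' per-cell drag at each activation temperature, deformity-scan counting,
#' then every statistical comparison - and collects all intermediate tables
#' and fitted models.
#'
#' Fitted comparisons:
#' * deformity proportion vs acclimation group (binomial GLM);
#' * each morphometric measure vs group (mixed models, log scale for the
#'   absolute sizes);
#' * VAP vs each morphology ratio at each activation temperature (linear
#'   models; acclimation added for the flagellum-to-head-area ratio, which
#'   is the measure that can differ between groups);
#' * mean drag vs acclimation x activation (mixed model) with
#'   least-squares-means activation contrasts within each group.
#'
#' @param study A [simulate_study()] result, or any list with compatible
#'   `cells`, `males`, `fields`, `design` elements.
#' @param viscosity Viscosity table (`temp_C`, `mu_Pa_s`).
#' @param viscosity_mode `"bracket_mean"` or `"linear"`; see
#'   [viscosity_at()].
#' @param df_method df method for post-hoc contrasts.
#' @return A list with class `"sperm_analysis"`: tables (`derived`,
#'   `male_summary`, `drag`, `drag_means`, `deformity_counts`,
#'   `deformity_tables`), fitted comparisons (`fits`, a named list of
#'   [sperm_fit]s), and `contrasts`.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' ana <- analyze_study(study)
#' tidy(ana$fits$morphology_ratio_LF_AH)
analyze_study <- function(study,
                          viscosity = water_viscosity_table(),
                          viscosity_mode = c("bracket_mean", "linear"),
                          df_method = c("satterthwaite", "kenward-roger")) {
  viscosity_mode <- match.arg(viscosity_mode)
  df_method <- match.arg(df_method)
  design <- study$design

  derived <- derive_cells(study$cells)
  male_summary <- summarize_males(derived) %>%
    left_join(study$males, by = intersect(c("male_id", "group"),
                                          names(study$males)))
  drag <- drag_table(derived, study$males, table = viscosity,
                     activation_temps = design$activation_temps,
                     mode = viscosity_mode)
  drag_means <- summarize_drag(drag, study$males)
  counts <- deformity_counts(study$fields, target = design$target_scan_count,
                             males = study$males)
  deformity_tables <- tabulate_deformity(counts)

  fits <- list(deformity = compare_deformity(counts))
  for (m in names(MORPHOLOGY_MEASURES)) {
    fits[[paste0("morphology_", m)]] <- compare_morphology(derived, m)
  }
  for (temp in design$activation_temps) {
    vap_col <- sprintf("vap_um_per_s_at_%gC", temp)
    fits[[sprintf("speed_LF_LH_%gC", temp)]] <- speed_vs_morphology(
      male_summary, ratio = "mean_ratio_LF_LH", vap_col = vap_col,
      activation_temp_C = temp, include_acclimation = FALSE
    )
    fits[[sprintf("speed_LF_AH_%gC", temp)]] <- speed_vs_morphology(
      male_summary, ratio = "mean_ratio_LF_AH_per_um", vap_col = vap_col,
      activation_temp_C = temp, include_acclimation = TRUE
    )
  }
  fits$drag <- drag_model(drag_means)
  contrasts <- activation_contrasts(fits$drag, df_method = df_method)

  structure(
    list(
      derived = derived, male_summary = male_summary,
      drag = drag, drag_means = drag_means,
      deformity_counts = counts, deformity_tables = deformity_tables,
      fits = fits, contrasts = contrasts,
      seed = study$seed, design = design
    ),
    class = "sperm_analysis"
  )
}

#' @export
print.sperm_analysis <- function(x, ...) {
  cat(sprintf("<sperm_analysis> %d fits, %d cells, %d drag records\n",
              length(x$fits), nrow(x$derived), nrow(x$drag)))
  invisible(x)
}

fit_results_table <- function(fits) {
  purrr::imap(fits, function(f, nm) mutate(tidy(f), stage = nm)) %>%
    bind_rows() %>%
    select("stage", dplyr::everything())
}

#' Render a plain-text analysis report
#'
#' One deterministic text report with four sections mirroring the study's
#' result tables - deformity proportions, morphology comparisons, speed
#' models, the drag model - plus the post-hoc activation contrasts.
#'
#' @param analysis A [analyze_study()] result.
#' @return Character vector of report lines.
#' @export
report_text <- function(analysis) {
  fmt <- function(x, d = 4) {
    ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"), x))
  }
  term_lines <- function(fit) {
    t <- tidy(fit)
    c(sprintf("  %-32s est=%s se=%s stat=%s df=%s p=%s",
              t$term, fmt(t$estimate), fmt(t$std_error), fmt(t$statistic),
              fmt(t$df, 1), fmt(t$p_value)),
      if (length(fit$flags)) sprintf("  flags: %s", paste(fit$flags, collapse = "; ")))
  }
  g <- analysis$deformity_tables$by_group
  lines <- c(
    "# Sperm morphology, deformity and head-drag analysis",
    "",
    "## 1. Deformed spermatozoa",
    sprintf("  group=%s n_males=%d prop_deformed=%s (kink=%s coil=%s short=%s tailless=%s)",
            g$group, g$n_males, fmt(g$proportion_deformed),
            fmt(g$prop_kink), fmt(g$prop_coil), fmt(g$prop_short),
            fmt(g$prop_tailless)),
    "  Binomial GLM, deformity proportion ~ acclimation group:",
    term_lines(analysis$fits$deformity),
    "",
    "## 2. Sperm morphology vs acclimation group"
  )
  for (m in names(MORPHOLOGY_MEASURES)) {
    fit <- analysis$fits[[paste0("morphology_", m)]]
    lines <- c(lines,
               sprintf("  [%s, %s scale]", m, fit$transform),
               term_lines(fit))
  }
  lines <- c(lines, "", "## 3. Swimming speed vs morphology")
  speed_fits <- analysis$fits[grepl("^speed_", names(analysis$fits))]
  for (nm in names(speed_fits)) {
    lines <- c(lines, sprintf("  [%s, %s response]", nm,
                              speed_fits[[nm]]$transform),
               term_lines(speed_fits[[nm]]))
  }
  lines <- c(lines, "", "## 4. Drag force model",
             term_lines(analysis$fits$drag))
  if (!is.null(analysis$fits$drag$anova)) {
    an <- analysis$fits$drag$anova
    lines <- c(lines, "  Type III tests:",
               sprintf("    %-32s F=%s df=%s/%s p=%s", an$term,
                       fmt(an$statistic), fmt(an$df_num, 0),
                       fmt(an$df_den, 1), fmt(an$p_value)))
  }
  ctr <- analysis$contrasts
  lines <- c(lines, "", "## Post-hoc activation contrasts (LS means)",
             sprintf("  %s %s: est=%s se=%s t=%s df=%s p=%s",
                     ctr$acclimation, ctr$contrast, fmt(ctr$estimate),
                     fmt(ctr$std_error), fmt(ctr$statistic), fmt(ctr$df, 1),
                     fmt(ctr$p_value)))
  lines
}

# ---- deterministic CSV IO with metadata headers ----------------------------

format_csv_field <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    sprintf("%.15g", x)
  } else {
    as.character(x)
  }
}

write_csv_meta <- function(df, path, meta = list()) {
  header <- sprintf("# %s: %s", names(meta), unlist(meta))
  cols <- names(df)
  body <- do.call(paste, c(lapply(df, format_csv_field), sep = ","))
  writeLines(c(header, paste(cols, collapse = ","), body), path)
}

read_csv_meta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  as_tibble(utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE))
}

output_meta <- function(seed, design, effects = NULL) {
  list(
    tool = paste0("spermorph ", as.character(packageVersion("spermorph"))),
    seed = seed,
    config_hash = rlang::hash(list(design = unclass(design),
                                   effects = if (!is.null(effects)) unclass(effects)))
  )
}

flatten_config <- function(prefix, x) {
  out <- character()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) next
    if (!is.null(names(v)) && length(v) > 1) {
      out <- c(out, sprintf("%s.%s.%s: %.15g", prefix, nm, names(v), v))
    } else {
      out <- c(out, sprintf("%s.%s: %s", prefix, nm,
                            paste(format_csv_field(v), collapse = " ")))
    }
  }
  out
}

#' Write a simulated study to a directory of CSV files
#'
#' Writes `cells.csv`, `males.csv`, `fields.csv` and a key-value
#' `config.txt` (design, effects, seed). Every file carries a metadata
#' header (`# tool`, `# seed`, `# config_hash`) so outputs are
#' self-describing; reruns with the same seed are byte-identical.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- output_meta(study$seed, study$design, study$effects)
  write_csv_meta(study$cells, file.path(dir, "cells.csv"), meta)
  write_csv_meta(study$males, file.path(dir, "males.csv"), meta)
  write_csv_meta(study$fields, file.path(dir, "fields.csv"), meta)
  writeLines(
    c(sprintf("# %s: %s", names(meta), unlist(meta)),
      flatten_config("design", unclass(study$design)),
      flatten_config("effects", unclass(study$effects)),
      sprintf("seed: %d", study$seed)),
    file.path(dir, "config.txt")
  )
  invisible(dir)
}

parse_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  kv <- strsplit(lines, ": ", fixed = TRUE)
  setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

#' Read a study directory written by [write_study()]
#'
#' Validates the schema of each file and reconstructs the design from
#' `config.txt`. Schema violations raise errors naming the file and the
#' missing or offending column.
#'
#' @param dir Directory containing `cells.csv`, `males.csv`, `fields.csv`,
#'   `config.txt`.
#' @return A `"sperm_study"`-shaped list (without the `effects` element).
#' @export
read_study <- function(dir) {
  cells <- read_csv_meta(file.path(dir, "cells.csv"))
  males <- read_csv_meta(file.path(dir, "males.csv"))
  fields <- read_csv_meta(file.path(dir, "fields.csv"))
  for (spec in list(
    list(df = cells, file = "cells.csv",
         cols = c("male_id", "group", "cell_id", "L_H_um", "W_H_um", "L_F_um", "category")),
    list(df = males, file = "males.csv", cols = c("male_id", "group")),
    list(df = fields, file = "fields.csv",
         cols = c("male_id", "field_idx", DEFORMITY_CATEGORIES))
  )) {
    missing <- setdiff(spec$cols, names(spec$df))
    if (length(missing) > 0) {
      abort(sprintf("%s: missing column(s) %s.", spec$file,
                    paste(missing, collapse = ", ")))
    }
    if (nrow(spec$df) == 0) {
      abort(sprintf("%s: no data rows.", spec$file))
    }
  }
  bad <- which(!is.finite(cells$L_H_um) | cells$L_H_um <= 0 |
                 !is.finite(cells$W_H_um) | cells$W_H_um <= 0 |
                 !is.finite(cells$L_F_um) | cells$L_F_um < 0)
  if (length(bad) > 0) {
    abort(sprintf("cells.csv: invalid measurement at row %d (columns L_H_um/W_H_um/L_F_um).",
                  bad[1]))
  }
  cfg <- parse_config(file.path(dir, "config.txt"))
  num <- function(key, default) {
    if (is.null(cfg[[key]])) default else as.numeric(strsplit(cfg[[key]], " ")[[1]])
  }
  design <- study_design(
    n_males_per_group = num("design.n_males_per_group", 8),
    n_cells_per_male = num("design.n_cells_per_male", 40),
    acclimation_temps = num("design.acclimation_temps", c(8, 13)),
    activation_temps = num("design.activation_temps", c(8, 13)),
    target_scan_count = num("design.target_scan_count", 100),
    cells_per_field_mean = num("design.cells_per_field_mean", 25),
    excluded_per_field_mean = num("design.excluded_per_field_mean", 1)
  )
  structure(
    list(cells = cells, males = males, fields = fields, design = design,
         effects = NULL, seed = as.integer(num("seed", NA))),
    class = "sperm_study"
  )
}

#' Pipeline stage: simulate a study to disk
#'
#' @param outdir Output directory.
#' @param design,effects,seed See [simulate_study()].
#' @return The study, invisibly.
#' @export
run_simulate <- function(outdir, design = study_design(),
                         effects = effect_config(), seed = 1) {
  study <- simulate_study(design, effects, seed)
  write_study(study, outdir)
  invisible(study)
}

#' Pipeline stage: analyse a study directory to disk
#'
#' Reads a study directory, runs [analyze_study()] and writes all derived
#' tables (`derived_cells.csv`, `drag.csv`, `drag_per_male.csv`,
#' `deformity_counts.csv`), per-model term tables under `results/`, the
#' contrast table, and `report.md`.
#'
#' @param indir Study directory ([write_study()] layout).
#' @param outdir Output directory (may equal `indir`).
#' @param ... Passed to [analyze_study()].
#' @return The `sperm_analysis`, invisibly.
#' @export
run_analyze <- function(indir, outdir = indir, ...) {
  study <- read_study(indir)
  analysis <- analyze_study(study, ...)
  dir.create(file.path(outdir, "results"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- output_meta(study$seed, study$design)
  write_csv_meta(analysis$derived, file.path(outdir, "derived_cells.csv"), meta)
  write_csv_meta(analysis$drag, file.path(outdir, "drag.csv"), meta)
  write_csv_meta(analysis$drag_means, file.path(outdir, "drag_per_male.csv"), meta)
  write_csv_meta(analysis$deformity_counts,
                 file.path(outdir, "deformity_counts.csv"), meta)
  write_csv_meta(fit_results_table(analysis$fits),
                 file.path(outdir, "results", "model_terms.csv"), meta)
  write_csv_meta(analysis$contrasts,
                 file.path(outdir, "results", "contrasts.csv"), meta)
  writeLines(report_text(analysis), file.path(outdir, "report.md"))
  invisible(analysis)
}

#' Pipeline stage: re-render the report from written results
#'
#' Builds a human-readable summary from the CSV outputs of [run_analyze()],
#' with an explicit "stage missing" note for any absent stage.
#'
#' @param dir Directory holding `run_analyze()` outputs.
#' @param file Optional path to also write the report to.
#' @return Character vector of report lines.
#' @export
run_report <- function(dir, file = file.path(dir, "report.md")) {
  fmt_tbl <- function(df) {
    cols <- names(df)
    vals <- do.call(paste, c(lapply(df, format_csv_field), sep = " | "))
    c(paste("  ", paste(cols, collapse = " | ")), paste("  ", vals))
  }
  section <- function(title, path) {
    p <- file.path(dir, path)
    if (!file.exists(p)) {
      return(c(title, sprintf("  [stage missing: %s not found]", path), ""))
    }
    c(title, fmt_tbl(read_csv_meta(p)), "")
  }
  lines <- c(
    "# Sperm morphology, deformity and head-drag analysis",
    "",
    section("## 1. Deformed spermatozoa (per-male scan counts)",
            "deformity_counts.csv"),
    section("## 2-4. Model terms (deformity, morphology, speed, drag)",
            file.path("results", "model_terms.csv")),
    section("## Post-hoc activation contrasts (LS means)",
            file.path("results", "contrasts.csv"))
  )
  if (!is.null(file)) {
    writeLines(lines, file)
  }
  invisible(lines)
}
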
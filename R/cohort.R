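cohort_columns <- c("rat_id", "genotype", "sex", "age_weeks", "diagnosis",
                    "loh", "loh_type", "chromothripsis", "ct_chroms",
                    "bfb", "bfb_chroms", "amplified_oncogenes")

#' Load a cohort table of per-tumor records
#'
#' Reads the tab-separated cohort dialect with columns `rat_id`,
#' `genotype`, `sex`, `age_weeks`, `diagnosis`, `loh`, `loh_type`,
#' `chromothripsis`, `ct_chroms`, `bfb`, `bfb_chroms`,
#' `amplified_oncogenes`. Flags are `YES`/`NO`; list fields are
#' comma-separated; `-` marks an empty field and `ND` a missing
#' determination (parsed to `NA`). A packaged example transcribing a
#' published 26-tumor p53-knockout rat cohort ships as
#' `system.file("extdata", "table1.tsv", package = "karyosig")`.
#'
#' @param path Path to the cohort TSV.
#' @return A validated tibble of tumor records; flags become logicals,
#'   `ND` becomes `NA`.
#' @export
read_cohort_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        comment = "#", show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    warn("cohort table has an empty data section")
    out <- tibble(rat_id = character(), genotype = character(), sex = character(),
                  age_weeks = numeric(), diagnosis = character(), loh = logical(),
                  loh_type = character(), chromothripsis = logical(),
                  ct_chroms = character(), bfb = logical(), bfb_chroms = character(),
                  amplified_oncogenes = character())
    return(out)
  }
  bad_gt <- !df$genotype %in% c("+/-", "-/-")
  if (any(bad_gt)) {
    abort(paste0("unknown genotype token '", df$genotype[which(bad_gt)[1]],
                 "' in row ", df$rat_id[which(bad_gt)[1]]))
  }
  blank <- function(x) ifelse(is.na(x) | x %in% c("-", ""), "", x)
  nd_na <- function(x) ifelse(x %in% c("ND", "-", ""), NA_character_, x)
  flag <- function(x, col) {
    x <- toupper(blank(x))
    if (!all(x %in% c("YES", "NO", ""))) abort(paste0("bad ", col, " flag; use YES/NO"))
    x == "YES"
  }
  out <- tibble(rat_id = df$rat_id,
                genotype = df$genotype,
                sex = nd_na(df$sex),
                age_weeks = suppressWarnings(as.numeric(df$age_weeks)),
                diagnosis = nd_na(df$diagnosis),
                loh = flag(df$loh, "loh"),
                loh_type = ifelse(blank(df$loh_type) == "", NA_character_, df$loh_type),
                chromothripsis = flag(df$chromothripsis, "chromothripsis"),
                ct_chroms = blank(df$ct_chroms),
                bfb = flag(df$bfb, "bfb"),
                bfb_chroms = blank(df$bfb_chroms),
                amplified_oncogenes = blank(df$amplified_oncogenes))
  bad_ct <- out$chromothripsis != (out$ct_chroms != "")
  if (any(bad_ct)) {
    abort(paste0("chromothripsis flag and affected-chromosome list disagree for rat ",
                 out$rat_id[which(bad_ct)[1]]))
  }
  bad_bfb <- out$bfb != (out$bfb_chroms != "")
  if (any(bad_bfb)) {
    abort(paste0("bfb flag and affected-chromosome list disagree for rat ",
                 out$rat_id[which(bad_bfb)[1]]))
  }
  out
}

#' Write tumor records in the cohort-table dialect
#'
#' Inverse of [read_cohort_table()]; re-loading the written file
#' reproduces the records exactly.
#'
#' @param records Tumor-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  df <- records[, cohort_columns]
  yn <- function(x) ifelse(x, "YES", "NO")
  dash <- function(x) ifelse(is.na(x) | x == "", "-", x)
  df <- mutate(df,
               sex = dash(.data$sex),
               age_weeks = ifelse(is.na(.data$age_weeks), "ND", .data$age_weeks),
               diagnosis = ifelse(is.na(.data$diagnosis), "ND", .data$diagnosis),
               loh = yn(.data$loh),
               loh_type = dash(.data$loh_type),
               chromothripsis = yn(.data$chromothripsis),
               ct_chroms = dash(.data$ct_chroms),
               bfb = yn(.data$bfb),
               bfb_chroms = dash(.data$bfb_chroms),
               amplified_oncogenes = dash(.data$amplified_oncogenes))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Summarize a tumor cohort
#'
#' Cross-tabulates per-tumor records by genotype: sample counts, tumor
#' diagnoses, chromothripsis / BFB / LOH-mechanism counts, and the
#' BFB-chromothripsis co-occurrence summary.
#'
#' @param records Tumor-record tibble (see [read_cohort_table()]).
#' @return An object of class `cohort_summary`: a list of tibbles
#'   `by_genotype`, `diagnosis_counts`, `signature_counts`,
#'   `loh_type_counts`, `cooccurrence`, `headline`. Use [tidy()] for the
#'   long count table and [glance()] for the one-row headline.
#' @export
summarize_cohort <- function(records) {
  records <- as_tibble(records)
  by_genotype <- count(records, .data$genotype, name = "n_tumors")
  diagnosis_counts <- records |>
    filter(!is.na(.data$diagnosis)) |>
    count(.data$genotype, .data$diagnosis, name = "n")
  signature_counts <- records |>
    group_by(.data$genotype) |>
    summarise(n_tumors = dplyr::n(),
              n_chromothripsis = sum(.data$chromothripsis),
              n_bfb = sum(.data$bfb),
              n_loh = sum(.data$loh), .groups = "drop")
  loh_type_counts <- records |>
    filter(!is.na(.data$loh_type)) |>
    count(.data$genotype, .data$loh_type, name = "n")
  cooc <- cooccurrence_summary(records)
  headline <- tibble(
    n_tumors = nrow(records),
    n_het = sum(records$genotype == "+/-"),
    n_hom = sum(records$genotype == "-/-"),
    n_ct_het = sum(records$chromothripsis & records$genotype == "+/-"),
    n_ct_hom = sum(records$chromothripsis & records$genotype == "-/-"),
    n_bfb = cooc$n_bfb,
    n_bfb_with_ct = cooc$n_bfb_with_ct,
    n_shared_chrom = cooc$n_shared_chrom,
    n_loh_by_ct = sum(!is.na(records$loh_type) &
                        records$loh_type == "affected by chromothripsis"))
  structure(list(by_genotype = by_genotype,
                 diagnosis_counts = diagnosis_counts,
                 signature_counts = signature_counts,
                 loh_type_counts = loh_type_counts,
                 cooccurrence = cooc,
                 headline = headline),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  h <- x$headline
  cat(sprintf("  %d tumors (%d +/-, %d -/-)\n", h$n_tumors, h$n_het, h$n_hom))
  cat(sprintf("  chromothripsis: %d in +/- vs %d in -/-\n", h$n_ct_het, h$n_ct_hom))
  cat(sprintf("  BFB: %d tumors; %d also chromothriptic; %d share an affected chromosome\n",
              h$n_bfb, h$n_bfb_with_ct, h$n_shared_chrom))
  cat(sprintf("  LOH via chromothripsis: %d\n", h$n_loh_by_ct))
  invisible(x)
}

#' @export
#' @method tidy cohort_summary
tidy.cohort_summary <- function(x, ...) {
  dplyr::bind_rows(
    mutate(x$diagnosis_counts, table = "diagnosis", .before = 1) |>
      dplyr::rename(level = "diagnosis"),
    mutate(x$loh_type_counts, table = "loh_type", .before = 1) |>
      dplyr::rename(level = "loh_type"),
    x$signature_counts |>
      tidyr::pivot_longer(-"genotype", names_to = "level", values_to = "n") |>
      mutate(table = "signature", .before = 1))
}

#' @export
#' @method glance cohort_summary
glance.cohort_summary <- function(x, ...) x$headline
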
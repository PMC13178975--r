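#' Matched exposure/outcome GWAS summary statistics
#'
#' A summary pair is the sole real-data input of MR-SimSS: one row per
#' LD-pruned variant with the variant-exposure and variant-outcome
#' association estimates and their standard errors, matched 1:1 on variant
#' ID, plus the two GWAS sample sizes carried as attributes. Effects are
#' assumed to come from linear or logistic regression on standardized
#' genotypes; the package performs no LD pruning and no genotype-scale
#' conversion itself.
#'
#' @param data A data frame with columns `variant_id`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y` and optionally `maf`.
#' @param n_x,n_y Exposure and outcome GWAS sample sizes (single positive
#'   counts; per-variant sample sizes are not supported).
#'
#' @return A tibble of class `summary_pair` with attributes `n_x`, `n_y`
#'   and (after reading from files) `load_report`.
#' @export
#' @examples
#' pair <- summary_pair(
#'   data.frame(
#'     variant_id = c("rs1", "rs2"),
#'     beta_x = c(0.02, -0.01), se_x = c(0.004, 0.004),
#'     beta_y = c(0.006, -0.002), se_y = c(0.004, 0.004)
#'   ),
#'   n_x = 200000, n_y = 200000
#' )
#' pair
summary_pair <- function(data, n_x, n_y) {
  data <- tibble::as_tibble(data)
  required <- c("variant_id", "beta_x", "se_x", "beta_y", "se_y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "summary pair is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "mrsimss_format_error")
  }
  if (nrow(data) == 0) {
    abort("summary pair contains no variants", class = "mrsimss_empty_error")
  }
  keep <- c(required, intersect("maf", names(data)),
            intersect(c("beta_x_true", "beta_y_true"), names(data)))
  data <- data[keep]
  num_cols <- setdiff(keep, "variant_id")
  ok <- rowSums(is.na(data[num_cols])) == 0
  n_missing <- sum(!ok)
  data <- data[ok, , drop = FALSE]
  if (nrow(data) == 0) {
    abort("all variants had missing values", class = "mrsimss_empty_error")
  }
  if (anyDuplicated(data$variant_id)) {
    abort("variant_id values must be unique", class = "mrsimss_format_error")
  }
  if (any(!is.finite(data$se_x)) || any(!is.finite(data$se_y)) ||
      any(data$se_x <= 0) || any(data$se_y <= 0)) {
    abort("standard errors must be strictly positive and finite",
          class = "mrsimss_format_error")
  }
  check_count(n_x, "n_x")
  check_count(n_y, "n_y")
  structure(
    data,
    n_x = as.double(n_x),
    n_y = as.double(n_y),
    n_dropped_missing = n_missing,
    class = c("summary_pair", class(tibble::tibble()))
  )
}

check_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0 || x != round(x)) {
    abort(paste0(name, " must be a single positive count"),
          class = "mrsimss_format_error")
  }
  invisible(x)
}

#' @export
print.summary_pair <- function(x, ...) {
  cat(sprintf(
    "# summary_pair: %d variants, n_x = %s, n_y = %s\n",
    nrow(x), format(attr(x, "n_x")), format(attr(x, "n_y"))
  ))
  NextMethod()
}

# default GWAS-SSF-like column aliases, matched case-insensitively
default_column_aliases <- list(
  variant_id = c("variant_id", "rsid", "rs_id", "snp", "id", "markername"),
  beta = c("beta", "b", "effect", "effect_size"),
  se = c("se", "standard_error", "stderr", "sebeta"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1"),
  other_allele = c("other_allele", "oa", "a2", "allele2", "non_effect_allele"),
  maf = c("effect_allele_frequency", "eaf", "maf", "freq", "af")
)

resolve_columns <- function(nms, column_map, path,
                            aliases = default_column_aliases) {
  out <- list()
  lower <- tolower(nms)
  for (field in names(aliases)) {
    cand <- column_map[[field]] %||% aliases[[field]]
    hit <- nms[match(tolower(cand), lower, nomatch = 0L)]
    if (!is.null(column_map[[field]]) && length(hit) == 0) {
      abort(sprintf("mapped column '%s' (%s) not found in %s",
                    column_map[[field]], field, path),
            class = "mrsimss_format_error")
    }
    out[[field]] <- if (length(hit) > 0) hit[[1]] else NA_character_
  }
  for (field in c("variant_id", "beta", "se")) {
    if (is.na(out[[field]])) {
      abort(sprintf("could not locate a '%s' column in %s", field, path),
            class = "mrsimss_format_error")
    }
  }
  out
}

read_gwas_table <- function(path, column_map, role) {
  # read as character and convert with as.numeric(): exact (correctly
  # rounded) double parsing, so written files round-trip bit-identically
  raw <- readr::read_delim(
    path, delim = NULL,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA", "NaN", "."), progress = FALSE, show_col_types = FALSE
  )
  # also auto-detect this package's own output format (beta_x/se_x/...)
  aliases <- default_column_aliases
  aliases$beta <- c(aliases$beta, paste0("beta_", role))
  aliases$se <- c(aliases$se, paste0("se_", role))
  cols <- resolve_columns(names(raw), column_map, path, aliases)
  out <- tibble::tibble(
    variant_id = as.character(raw[[cols$variant_id]]),
    beta = as.numeric(raw[[cols$beta]]),
    se = as.numeric(raw[[cols$se]])
  )
  if (!is.na(cols$effect_allele)) {
    out$effect_allele <- toupper(as.character(raw[[cols$effect_allele]]))
  }
  if (!is.na(cols$other_allele)) {
    out$other_allele <- toupper(as.character(raw[[cols$other_allele]]))
  }
  if (!is.na(cols$maf)) out$maf <- as.numeric(raw[[cols$maf]])
  present <- intersect(c("beta", "se", "maf"), names(out))
  names(out)[match(present, names(out))] <- paste0(present, "_", role)
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Read and harmonize a matched GWAS summary-statistics pair
#'
#' Reads two delimited summary-statistics files (tab or comma separated,
#' optionally gzipped), auto-detecting GWAS-SSF-like column names, inner
#' joins them on variant ID and harmonizes outcome effects to the exposure
#' effect allele. Outcome rows whose effect/other alleles are swapped
#' relative to the exposure are sign-flipped; strand-ambiguous (A/T, C/G)
#' variants are dropped when allele columns are available; rows with missing
#' estimates are dropped and counted.
#'
#' @param exposure_path,outcome_path Paths to the exposure and outcome
#'   summary-statistics files.
#' @param n_x,n_y GWAS sample sizes of the exposure and outcome studies.
#' @param column_map Optional named list overriding column auto-detection;
#'   recognised fields: `variant_id`, `beta`, `se`, `effect_allele`,
#'   `other_allele`, `maf`. Applied to both files.
#' @return A [summary_pair] whose `load_report` attribute records the
#'   number of rows read, matched, flipped and dropped.
#' @export
read_summary_pair <- function(exposure_path, outcome_path, n_x, n_y,
                              column_map = list()) {
  exp_tab <- read_gwas_table(exposure_path, column_map, "x")
  out_tab <- read_gwas_table(outcome_path, column_map, "y")
  n_read_x <- nrow(exp_tab)
  n_read_y <- nrow(out_tab)
  if (n_read_x == 0 || n_read_y == 0) {
    abort("an input file contained no data rows", class = "mrsimss_empty_error")
  }

  joined <- dplyr::inner_join(exp_tab, out_tab, by = "variant_id",
                              suffix = c("_x", "_y"))
  if (nrow(joined) == 0) {
    abort("no variants shared between exposure and outcome files",
          class = "mrsimss_empty_error")
  }

  n_flipped <- 0L
  n_palindromic <- 0L
  n_mismatch <- 0L
  have_alleles <- all(c("effect_allele_x", "other_allele_x",
                        "effect_allele_y", "other_allele_y") %in% names(joined))
  if (have_alleles) {
    pal <- is_palindromic(joined$effect_allele_x, joined$other_allele_x)
    n_palindromic <- sum(pal, na.rm = TRUE)
    joined <- joined[!pal %in% TRUE, , drop = FALSE]
    same <- joined$effect_allele_y == joined$effect_allele_x &
      joined$other_allele_y == joined$other_allele_x
    swapped <- joined$effect_allele_y == joined$other_allele_x &
      joined$other_allele_y == joined$effect_allele_x
    n_mismatch <- sum(!(same | swapped), na.rm = TRUE)
    n_flipped <- sum(swapped, na.rm = TRUE)
    joined$beta_y[swapped %in% TRUE] <- -joined$beta_y[swapped %in% TRUE]
    if ("maf_y" %in% names(joined)) {
      joined$maf_y[swapped %in% TRUE] <- 1 - joined$maf_y[swapped %in% TRUE]
    }
    joined <- joined[(same | swapped) %in% TRUE, , drop = FALSE]
  }
  if (nrow(joined) == 0) {
    abort("no variants left after allele harmonization",
          class = "mrsimss_empty_error")
  }

  maf <- if ("maf_x" %in% names(joined)) joined$maf_x else NULL
  dat <- tibble::tibble(
    variant_id = joined$variant_id,
    beta_x = joined$beta_x, se_x = joined$se_x,
    beta_y = joined$beta_y, se_y = joined$se_y
  )
  if (!is.null(maf)) dat$maf <- pmin(maf, 1 - maf)
  pair <- summary_pair(dat, n_x = n_x, n_y = n_y)

  if (!is.null(maf) && stats::median(abs(pair$se_x) *
        sqrt(2 * pair$maf * (1 - pair$maf) * n_x), na.rm = TRUE) > 2) {
    warn(paste(
      "standard errors look allele-scaled rather than standardized-genotype",
      "scaled; MR-SimSS assumes standardized genotypes"
    ))
  }

  attr(pair, "load_report") <- tibble::tibble(
    n_read_exposure = n_read_x,
    n_read_outcome = n_read_y,
    n_matched = nrow(pair),
    n_flipped = n_flipped,
    n_dropped_palindromic = n_palindromic,
    n_dropped_mismatch = n_mismatch,
    n_dropped_missing = attr(pair, "n_dropped_missing")
  )
  pair
}

#' Write a summary pair to a tab-delimited file
#'
#' Writes the fixed column order `variant_id, beta_x, se_x, beta_y, se_y[,
#' maf]` at full double precision, so that re-reading reproduces every
#' numeric field exactly.
#'
#' @param pair A [summary_pair].
#' @param path Output file path (`.gz` suffix compresses transparently).
#' @return `pair`, invisibly.
#' @export
write_summary_pair <- function(pair, path) {
  stopifnot(is.data.frame(pair))
  cols <- c("variant_id", "beta_x", "se_x", "beta_y", "se_y",
            intersect("maf", names(pair)))
  if (!all(cols[1:5] %in% names(pair))) {
    abort("not a summary pair: required columns missing",
          class = "mrsimss_format_error")
  }
  out <- tibble::as_tibble(pair)[cols]
  # full precision so that read(write(pair)) round-trips bit-exactly
  for (nm in setdiff(cols, "variant_id")) {
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(pair)
}
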
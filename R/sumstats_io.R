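#' Read GWAS summary statistics from a TSV file
#'
#' Reads a tab-separated table of per-SNP association statistics, maps
#' arbitrary source headers onto the canonical column set, validates every row
#' and returns a `sumstats` object. Rows violating the per-SNP invariants
#' (`se > 0`, `ea != oa`, `0 < eaf < 1` when present, `0 < pval <= 1`,
#' `n > 0`, single-base alleles) are dropped with a logged count; duplicate
#' rsIDs keep the first occurrence only.
#'
#' @param path Path to a TSV file with one row per SNP.
#' @param column_map Named character vector mapping canonical names
#'   (`rsid`, `chrom`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n`)
#'   to the file's headers. Defaults to the identity map. `eaf`, `chrom` and
#'   `pos` are optional; the rest are mandatory.
#' @param trait_id Label for the trait; defaults to the file name.
#' @param trait_type `"binary"` (betas are log-odds) or `"continuous"`
#'   (betas in SD units).
#' @param quiet Suppress per-stage logging.
#' @return A `sumstats` object: a data frame with columns `rsid`, `chrom`,
#'   `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n` and attributes
#'   `trait_id` and `trait_type`.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = NULL,
                          trait_type = c("continuous", "binary"),
                          quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  canon <- c("rsid", "chrom", "pos", "ea", "oa", "eaf", "beta", "se",
             "pval", "n")
  if (is.null(column_map)) {
    column_map <- stats::setNames(canon, canon)
  }
  mandatory <- c("rsid", "ea", "oa", "beta", "se", "pval", "n")
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map) > 0) {
    stop("column_map lacks mandatory entries: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(column_map[mandatory]), names(raw))
  if (length(absent) > 0) {
    stop("mapped columns absent from file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(rsid = as.character(raw[[column_map[["rsid"]]]]),
                   stringsAsFactors = FALSE)
  opt_col <- function(name, default) {
    if (name %in% names(column_map) && column_map[[name]] %in% names(raw)) {
      raw[[column_map[[name]]]]
    } else {
      rep(default, nrow(raw))
    }
  }
  df$chrom <- as.character(opt_col("chrom", NA_character_))
  df$pos <- as.numeric(opt_col("pos", NA_real_))
  df$ea <- toupper(as.character(raw[[column_map[["ea"]]]]))
  df$oa <- toupper(as.character(raw[[column_map[["oa"]]]]))
  df$eaf <- as.numeric(opt_col("eaf", NA_real_))
  df$beta <- as.numeric(raw[[column_map[["beta"]]]])
  df$se <- as.numeric(raw[[column_map[["se"]]]])
  df$pval <- as.numeric(raw[[column_map[["pval"]]]])
  df$n <- as.numeric(raw[[column_map[["n"]]]])

  validate_sumstats(df, trait_id = trait_id %||% basename(path),
                    trait_type = trait_type, quiet = quiet)
}

#' Build a validated `sumstats` object from a data frame
#'
#' Applies the same row-level validation as [read_sumstats()]; used by the
#' synthetic generator and by callers holding in-memory tables.
#'
#' @param df Data frame with the canonical columns.
#' @inheritParams read_sumstats
#' @return A `sumstats` object.
#' @export
validate_sumstats <- function(df, trait_id = "trait",
                              trait_type = c("continuous", "binary"),
                              quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  for (col in c("chrom", "pos", "eaf")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  n_in <- nrow(df)
  allele_class <- vapply(seq_len(nrow(df)), function(i) {
    validate_alleles(df$ea[i], df$oa[i])
  }, character(1))
  ok <- !is.na(df$rsid) & nzchar(df$rsid) &
    allele_class != "invalid" &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
    is.finite(df$n) & df$n > 0 &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1))
  n_invalid <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(df$rsid)
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no valid SNP records remain for trait '", trait_id, "'",
         call. = FALSE)
  }
  if (!quiet && (n_invalid > 0 || n_dup > 0)) {
    message(sprintf("[%s] dropped %d invalid row(s), %d duplicate rsid(s); %d of %d retained",
                    trait_id, n_invalid, n_dup, nrow(df), n_in))
  }
  rownames(df) <- NULL
  structure(df[, c("rsid", "chrom", "pos", "ea", "oa", "eaf", "beta",
                   "se", "pval", "n")],
            trait_id = trait_id, trait_type = trait_type,
            n_dropped_invalid = n_invalid, n_dropped_duplicate = n_dup,
            class = c("sumstats", "data.frame"))
}

#' Classify an allele pair
#'
#' A pair is `palindromic` when the two alleles are strand complements of each
#' other (A/T or C/G), so strand orientation cannot be resolved from the
#' alleles alone; `invalid` when either allele is not a single base in
#' A/C/G/T or the two are identical; `valid` otherwise.
#'
#' @param ea,oa Effect and other allele (single characters, case-insensitive).
#' @return One of `"valid"`, `"palindromic"`, `"invalid"`.
#' @export
validate_alleles <- function(ea, oa) {
  bases <- c("A", "C", "G", "T")
  ea <- toupper(as.character(ea))
  oa <- toupper(as.character(oa))
  if (is.na(ea) || is.na(oa) || !(ea %in% bases) || !(oa %in% bases) ||
      ea == oa) {
    return("invalid")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (comp[[ea]] == oa) "palindromic" else "valid"
}

#' Write a result table as TSV
#'
#' Fixed column order as supplied; floating-point columns rendered with 15
#' significant digits so the table round-trips losslessly through
#' [utils::read.delim()].
#'
#' @param table Non-empty data frame.
#' @param path Output path; parent directories are created.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("refusing to write an empty result table", call. = FALSE)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- table
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- sprintf("%.15g", out[[col]])
      out[[col]][out[[col]] == "NA"] <- NA
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a plain-text rsID exclusion list
#'
#' One rsID per line; blank lines and `#` comments ignored. Used for
#' confounder-associated SNP blacklists.
#'
#' @param path File path, or `NULL` for an empty list.
#' @return Character vector of rsIDs.
#' @export
read_exclusion_list <- function(path) {
  if (is.null(path)) return(character(0))
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
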
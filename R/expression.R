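#' Subject-level expression tables
#'
#' Expression data are stored long ("tidy"): one row per measurement, keyed by
#' (subject, age, treatment, gene, region). Values are expression levels in
#' arbitrary optical-density units. A group is the triple (gene, age,
#' treatment); subjects are nested within (age, treatment) and measured for
#' every gene and region.
#'
#' @name expression_table
NULL

GENES <- c("cfos", "arc")
AGES <- c("adolescent", "adult")
TREATMENTS <- c("saline", "D2", "D1Gs", "D1Gq", "D1Gs+D2", "D1Gq+D2")

EXPR_COLUMNS <- c("subject_id", "age", "treatment", "gene", "region", "value")

#' All group keys of the full factorial design
#'
#' @param genes,ages,treatments factor level vectors; defaults give the
#'   2 gene x 2 age x 6 treatment design (24 groups).
#' @return data frame with columns `gene`, `age`, `treatment`.
#' @export
group_keys <- function(genes = GENES, ages = AGES, treatments = TREATMENTS) {
  expand.grid(gene = genes, age = ages, treatment = treatments,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' A short, file-safe label for a group
#'
#' @param gene,age,treatment group key components.
#' @return character label, e.g. `"cfos_adult_D1Gq-D2"`.
#' @export
group_label <- function(gene, age, treatment) {
  paste(gene, age, gsub("+", "-", treatment, fixed = TRUE), sep = "_")
}

new_expression_table <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Construct and validate an expression table
#'
#' @param df data frame with columns `subject_id`, `age`, `treatment`,
#'   `gene`, `region`, `value`.
#' @param registry region registry used to resolve region ids
#'   (case-insensitive; canonicalized to the registry spelling).
#' @param allow_missing if `FALSE` (default) every subject must carry a value
#'   for every registry region and gene it appears with; if `TRUE`,
#'   incomplete subjects are kept and dropped later, listwise, when networks
#'   are built.
#' @return an `expression_table`.
#' @export
as_expression_table <- function(df, registry = default_region_registry(),
                                allow_missing = FALSE) {
  missing <- setdiff(EXPR_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("MissingColumn: expression table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[EXPR_COLUMNS]
  for (col in c("subject_id", "age", "treatment", "gene", "region")) {
    df[[col]] <- trimws(as.character(df[[col]]))
  }
  if (!is.numeric(df$value)) {
    suppressWarnings(num <- as.numeric(df$value))
    bad <- which(is.na(num) & !is.na(df$value))
    if (length(bad) > 0L) {
      stop("NonNumericValue: non-numeric expression value in row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    df$value <- num
  }
  bad <- which(!is.finite(df$value))
  if (length(bad) > 0L) {
    stop("NonNumericValue: missing or non-finite value in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  if (any(df$value < 0)) {
    bad <- which(df$value < 0)
    stop("NonNumericValue: negative expression value in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  df$region <- canonical_region_id(df$region, registry)

  key <- paste(df$subject_id, df$age, df$treatment, df$gene, df$region,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("DuplicateMeasurement: repeated (subject, gene, region) in row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }

  if (!allow_missing) {
    by_subj <- table(paste(df$subject_id, df$age, df$treatment, df$gene,
                           sep = "\r"))
    incomplete <- by_subj != nrow(registry)
    if (any(incomplete)) {
      who <- vapply(strsplit(names(by_subj)[incomplete], "\r", fixed = TRUE),
                    function(p) paste0(p[1L], " (", p[4L], ")"), "")
      stop("incomplete region panel for subject(s): ",
           paste(utils::head(unique(who), 10L), collapse = ", "),
           "; use allow_missing = TRUE to drop them listwise per network",
           call. = FALSE)
    }
  }
  new_expression_table(sort_expression(df))
}

sort_expression <- function(df) {
  df[order(df$gene, df$age, df$treatment, df$subject_id, df$region,
           method = "radix"), , drop = FALSE]
}

#' Read an expression table from a delimited text file
#'
#' Accepts TSV or CSV (sniffed from the header line) with header
#' `subject_id, age, treatment, gene, region, value`, UTF-8, decimal point.
#'
#' @inheritParams as_expression_table
#' @param path file path.
#' @return an `expression_table`.
#' @export
load_expression <- function(path, registry = default_region_registry(),
                            allow_missing = FALSE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", colClasses = "character")
  as_expression_table(df, registry, allow_missing = allow_missing)
}

#' Write an expression table to TSV
#'
#' Rows are sorted deterministically (gene, age, treatment, subject, region)
#' and values are written in full precision, so writing the same table twice
#' produces byte-identical files and `load_expression()` round-trips exactly.
#'
#' @param table an `expression_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path) {
  df <- sort_expression(as.data.frame(table))
  df$value <- sprintf("%.17g", df$value)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(EXPR_COLUMNS, collapse = "\t"), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  }
  invisible(path)
}

#' Convert a wide (region-per-column) table to the long format
#'
#' Convenience importer for spreadsheets laid out with one row per subject
#' and one column per region.
#'
#' @param df data frame with columns `subject_id`, `age`, `treatment`,
#'   `gene`, plus one numeric column per region id.
#' @inheritParams as_expression_table
#' @return an `expression_table`.
#' @export
wide_to_long <- function(df, registry = default_region_registry(),
                         allow_missing = FALSE) {
  id_cols <- c("subject_id", "age", "treatment", "gene")
  missing <- setdiff(id_cols, names(df))
  if (length(missing) > 0L) {
    stop("MissingColumn: wide table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  region_cols <- setdiff(names(df), id_cols)
  long <- stats::reshape(as.data.frame(df), direction = "long",
                         varying = region_cols, v.names = "value",
                         timevar = "region", times = region_cols,
                         idvar = id_cols)
  as_expression_table(long[EXPR_COLUMNS], registry,
                      allow_missing = allow_missing)
}

#' Extract the subjects-by-regions matrix for one group
#'
#' Subjects with any missing region are dropped listwise so the group has a
#' single consistent n; dropped subjects are reported via a message.
#'
#' @param table an `expression_table`.
#' @param gene,age,treatment group key.
#' @param registry region registry fixing region order.
#' @return numeric matrix, rows = subjects (named), columns = registry
#'   regions in registry order.
#' @export
group_matrix <- function(table, gene, age, treatment,
                         registry = default_region_registry()) {
  sel <- table$gene == gene & table$age == age & table$treatment == treatment
  sub <- table[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no rows for group (", gene, ", ", age, ", ", treatment, ")",
         call. = FALSE)
  }
  subjects <- sort(unique(sub$subject_id))
  regions <- registry$region_id
  m <- matrix(NA_real_, nrow = length(subjects), ncol = length(regions),
              dimnames = list(subjects, regions))
  m[cbind(match(sub$subject_id, subjects), match(sub$region, regions))] <-
    sub$value
  complete <- rowSums(is.na(m)) == 0L
  if (any(!complete)) {
    message("dropping subject(s) with incomplete region panel: ",
            paste(subjects[!complete], collapse = ", "))
  }
  m[complete, , drop = FALSE]
}

#' @export
print.expression_table <- function(x, ...) {
  grp <- unique(x[c("gene", "age", "treatment")])
  cat(sprintf("<expression_table> %d rows, %d group(s), %d region(s)\n",
              nrow(x), nrow(grp), length(unique(x$region))))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
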
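#' Locus metadata for a biallelic InDel panel
#'
#' @param locus_id character vector of marker identifiers (rs numbers).
#'   Must be non-empty and unique.
#' @param insertion_label,deletion_label allele names; recycled.
#' @return data.frame with columns `locus_id`, `insertion_label`,
#'   `deletion_label`.
#' @export
locus_meta <- function(locus_id, insertion_label = "I", deletion_label = "D") {
  locus_id <- as.character(locus_id)
  if (length(locus_id) == 0L || any(!nzchar(locus_id)) || any(is.na(locus_id))) {
    stop("locus_id must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(locus_id)) {
    stop("duplicate locus_id: ", paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(locus_id = locus_id,
             insertion_label = rep_len(as.character(insertion_label), length(locus_id)),
             deletion_label = rep_len(as.character(deletion_label), length(locus_id)))
}

#' Construct a genotype matrix of insertion-allele dosages
#'
#' The central genotype container: samples in rows, loci in columns, each
#' entry the number of insertion alleles carried (0, 1 or 2) or `NA` for a
#' failed typing.
#'
#' @param dosage integer matrix, samples x loci; entries in `{0, 1, 2, NA}`.
#' @param sample_ids character vector, one per row, unique.
#' @param loci either a character vector of locus ids or a [locus_meta()]
#'   data.frame, one entry per column.
#' @return object of class `genotype_matrix`: the integer dosage matrix with
#'   `dimnames` set and the locus metadata attached as attribute `"loci"`.
#' @export
genotype_matrix <- function(dosage, sample_ids, loci) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.character(loci)) loci <- locus_meta(loci)
  sample_ids <- as.character(sample_ids)
  if (nrow(dosage) != length(sample_ids)) {
    stop("dosage has ", nrow(dosage), " rows but ", length(sample_ids),
         " sample ids", call. = FALSE)
  }
  if (ncol(dosage) != nrow(loci)) {
    stop("dosage has ", ncol(dosage), " columns but ", nrow(loci), " loci",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("dosage out of {0,1,2} at sample '", sample_ids[idx[1]],
         "', locus '", loci$locus_id[idx[2]], "'", call. = FALSE)
  }
  dimnames(dosage) <- list(sample_ids, loci$locus_id)
  structure(dosage, loci = loci, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x), " samples x ", ncol(x), " loci; ",
      sum(is.na(x)), " missing entries\n", sep = "")
  invisible(x)
}

#' Per-locus genotype counts
#'
#' @param n_ii insertion homozygotes.
#' @param n_id heterozygotes.
#' @param n_dd deletion homozygotes.
#' @return object of class `genotype_counts`: list with `n_ii`, `n_id`,
#'   `n_dd` and total `n`.
#' @export
genotype_counts <- function(n_ii, n_id, n_dd) {
  cnt <- c(n_ii = n_ii, n_id = n_id, n_dd = n_dd)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  structure(list(n_ii = as.integer(n_ii), n_id = as.integer(n_id),
                 n_dd = as.integer(n_dd),
                 n = as.integer(n_ii + n_id + n_dd)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("<genotype_counts> II=", x$n_ii, " ID=", x$n_id, " DD=", x$n_dd,
      " (n=", x$n, ")\n", sep = "")
  invisible(x)
}

# dosage cell parser shared by read_genotype_table
.parse_dosage_cell <- function(cell, row, col) {
  cell <- trimws(cell)
  if (cell %in% c("NA", "", ".")) return(NA_integer_)
  if (cell %in% c("0", "1", "2")) return(as.integer(cell))
  if (grepl("/", cell, fixed = TRUE)) {
    alleles <- toupper(strsplit(cell, "/", fixed = TRUE)[[1]])
    if (length(alleles) == 2L && all(alleles %in% c("I", "D"))) {
      return(sum(alleles == "I"))
    }
  }
  stop("cannot parse genotype '", cell, "' at row ", row, ", column '", col,
       "'", call. = FALSE)
}

#' Read a genotype table from delimited text
#'
#' Expected layout: header row of locus ids, first column sample ids, one row
#' per sample. Cells may be dosage integers (0/1/2), allele pairs over the
#' insertion/deletion labels (`I/I`, `I/D`, `D/I`, `D/D`), or the missing
#' token `NA`.
#'
#' @param path file to read.
#' @param sep field separator; by default inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return [genotype_matrix()].
#' @export
read_genotype_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"")
  if (ncol(raw) < 1L) stop("genotype table has no columns", call. = FALSE)
  sample_ids <- raw[[1]]
  loci_ids <- colnames(raw)[-1]
  dosage <- matrix(NA_integer_, nrow = nrow(raw), ncol = length(loci_ids))
  for (j in seq_along(loci_ids)) {
    col <- raw[[j + 1L]]
    for (i in seq_along(col)) {
      dosage[i, j] <- .parse_dosage_cell(col[i], i, loci_ids[j])
    }
  }
  genotype_matrix(dosage, sample_ids, loci_ids)
}

#' Write a genotype table as delimited text
#'
#' Inverse of [read_genotype_table()]: dosage integers with `NA` as the
#' missing token, first column `sample_id`.
#'
#' @param x [genotype_matrix()].
#' @param path output file.
#' @param sep field separator (default comma).
#' @export
write_genotype_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "genotype_matrix"))
  ids <- rownames(x)
  if (is.null(ids)) ids <- character(nrow(x))  # 0-row matrices drop dimnames
  out <- data.frame(sample_id = ids, unclass(x)[, , drop = FALSE],
                    check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Tally genotype counts at one locus
#'
#' @param x [genotype_matrix()].
#' @param locus column index or locus id.
#' @return [genotype_counts()] over the non-missing samples at that locus.
#' @export
tabulate_counts <- function(x, locus) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.character(locus)) {
    j <- match(locus, colnames(x))
    if (is.na(j)) stop("unknown locus '", locus, "'", call. = FALSE)
  } else {
    j <- as.integer(locus)
    if (j < 1L || j > ncol(x)) stop("locus index out of range", call. = FALSE)
  }
  d <- x[, j]
  d <- d[!is.na(d)]
  if (length(d) == 0L) {
    stop("locus '", colnames(x)[j], "' has no typed samples", call. = FALSE)
  }
  genotype_counts(sum(d == 2L), sum(d == 1L), sum(d == 0L))
}

#' Reconstruct exact genotype counts from published per-locus summaries
#'
#' Published forensic tables report the insertion-allele frequency and the
#' observed heterozygosity to four decimals, not the underlying genotype
#' counts. Because the heterozygote count is `round(ho * n)` and the
#' insertion-allele count is `round(f_ins * 2n)`, both roundings are
#' invertible for realistic sample sizes, so the exact counts can be
#' recovered. When the recovered allele count and heterozygote count differ
#' in parity (impossible for real data; can only arise from rounding at a
#' half boundary), the allele count is nudged by one in the direction that
#' best preserves the printed frequency, decrementing on ties.
#'
#' @param f_ins printed insertion-allele frequency, in `[0, 1]`.
#' @param ho printed observed heterozygosity, in `[0, 1]`.
#' @param n number of typed diploid individuals.
#' @return [genotype_counts()] with attribute `parity_repaired` (logical).
#' @export
#' @examples
#' reconstruct_counts_from_summary(0.5038, 0.4504, 262)  # 73/118/71
reconstruct_counts_from_summary <- function(f_ins, ho, n) {
  stopifnot(f_ins >= 0, f_ins <= 1, ho >= 0, ho <= 1, n >= 1)
  n_id <- round_half_up(ho * n)
  a <- round_half_up(f_ins * 2 * n)
  repaired <- FALSE
  if ((a - n_id) %% 2 != 0) {
    candidates <- c(a - 1, a + 1)
    err <- abs(candidates / (2 * n) - f_ins)
    a <- if (err[1] <= err[2]) candidates[1] else candidates[2]
    repaired <- TRUE
  }
  n_ii <- (a - n_id) / 2
  n_dd <- n - n_id - n_ii
  if (n_ii < 0 || n_dd < 0 || a < 0 || a > 2 * n) {
    stop("inconsistent summary: f_ins=", f_ins, ", ho=", ho, ", n=", n,
         " yields a negative genotype count", call. = FALSE)
  }
  out <- genotype_counts(n_ii, n_id, n_dd)
  attr(out, "parity_repaired") <- repaired
  out
}

#' Construct a population x locus insertion-frequency table
#'
#' @param freq numeric matrix in `[0, 1]`, populations x loci.
#' @param population_ids character vector, one per row, unique.
#' @param loci character vector of locus ids or a [locus_meta()] data.frame.
#' @param sample_sizes diploid sample size per population, `>= 1`.
#' @return object of class `frequency_table`: the numeric matrix with
#'   dimnames plus attributes `sample_sizes` and `loci`.
#' @export
frequency_table <- function(freq, population_ids, loci, sample_sizes) {
  freq <- as.matrix(freq)
  if (is.character(loci)) loci <- locus_meta(loci)
  population_ids <- as.character(population_ids)
  if (nrow(freq) != length(population_ids) || ncol(freq) != nrow(loci)) {
    stop("frequency matrix dimensions do not match population/locus lists",
         call. = FALSE)
  }
  if (anyDuplicated(population_ids)) {
    stop("duplicate population id", call. = FALSE)
  }
  if (any(is.na(freq)) || any(freq < 0) || any(freq > 1)) {
    bad <- which(is.na(freq) | freq < 0 | freq > 1, arr.ind = TRUE)[1, ]
    stop("frequency outside [0,1] for population '", population_ids[bad[1]],
         "', locus '", loci$locus_id[bad[2]], "'", call. = FALSE)
  }
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) != nrow(freq) || any(sample_sizes < 1L)) {
    stop("sample_sizes must give one count >= 1 per population", call. = FALSE)
  }
  dimnames(freq) <- list(population_ids, loci$locus_id)
  structure(freq, sample_sizes = stats::setNames(sample_sizes, population_ids),
            loci = loci, class = c("frequency_table", "matrix", "array"))
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> ", nrow(x), " populations x ", ncol(x), " loci\n",
      sep = "")
  invisible(x)
}

#' Read a population x locus frequency table
#'
#' Layout: first column population id, last column `n` (diploid sample
#' size), remaining columns one insertion-allele frequency per locus.
#'
#' @param path file to read.
#' @param sep field separator; inferred from the extension by default.
#' @return [frequency_table()].
#' @export
read_frequency_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(raw) < 3L) {
    stop("frequency table needs population id, >=1 locus, and an 'n' column",
         call. = FALSE)
  }
  if (tolower(colnames(raw)[ncol(raw)]) != "n") {
    stop("last column must be the sample-size column 'n'", call. = FALSE)
  }
  loci <- colnames(raw)[-c(1L, ncol(raw))]
  frequency_table(as.matrix(raw[, loci, drop = FALSE]), raw[[1]], loci,
                  raw[[ncol(raw)]])
}

#' Write a frequency table as delimited text
#'
#' @param x [frequency_table()].
#' @param path output file.
#' @param sep field separator (default comma).
#' @export
write_frequency_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "frequency_table"))
  out <- data.frame(population_id = rownames(x), unclass(x)[, , drop = FALSE],
                    n = attr(x, "sample_sizes"), check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
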
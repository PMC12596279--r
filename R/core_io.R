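# Domain types, readers/writers and validation shared by all analysis stages.

COMPARTMENTS <- c("detritus", "water", "invertebrate", "negative_control")
LOCI <- c("16S", "18S")

#' Construct a validated ASV count table
#'
#' A count table is a samples x ASVs matrix of non-negative integer read
#' counts with unique sample ids as row names and unique ASV ids as column
#' names.  Validation failures enumerate every offending id or cell, not just
#' the first.
#'
#' @param counts numeric matrix (samples x ASVs) with dimnames.
#' @return the matrix with class `count_table`.
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  validate_count_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(counts))
  counts
}

validate_count_table <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs sample ids as row names and ASV ids as column names")
  problems <- character(0)
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  dup_a <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    problems <- c(problems, paste0("duplicate sample ids: ", id_list(dup_s)))
  if (length(dup_a))
    problems <- c(problems, paste0("duplicate ASV ids: ", id_list(dup_a)))
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts)))
    problems <- c(problems, "counts must be finite numbers")
  else {
    neg <- which(counts < 0, arr.ind = TRUE)
    if (nrow(neg))
      problems <- c(problems, paste0(
        "negative counts at (sample, ASV): ",
        id_list(paste0("(", rownames(counts)[neg[, 1]], ", ",
                       colnames(counts)[neg[, 2]], ")"))))
    frac <- which(counts %% 1 != 0, arr.ind = TRUE)
    if (nrow(frac))
      problems <- c(problems, paste0(
        "non-integer counts at (sample, ASV): ",
        id_list(paste0("(", rownames(counts)[frac[, 1]], ", ",
                       colnames(counts)[frac[, 2]], ")"))))
  }
  if (length(problems))
    stop("invalid count table:\n  ", paste(problems, collapse = "\n  "))
  invisible(counts)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d ASVs, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# strip the class so matrix arithmetic stays a plain matrix
ct_matrix <- function(x) {
  if (inherits(x, "count_table")) class(x) <- setdiff(class(x), "count_table")
  x
}

#' Read an ASV count table
#'
#' TSV dialect: first column holds sample ids, header row holds ASV ids.
#' BIOM support (via the `biomformat` package) expects the standard
#' observations-as-rows orientation and transposes to samples-as-rows.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose for TSV input whose rows are ASVs rather than samples.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom"), transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # observations x samples
    return(count_table(t(m)))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("malformed count table header in ", path,
         ": expected a sample id column plus at least one ASV column")
  ids <- df[[1L]]
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, colnames(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]))
    if (length(bad))
      stop("non-numeric count in column '", colnames(df)[j + 1L],
           "' at row(s) for sample(s): ", id_list(ids[bad]))
    m[, j] <- v
  }
  if (transpose) m <- t(m)
  count_table(m)
}

#' Write an ASV count table as TSV
#'
#' Inverse of [read_count_table()]; `read(write(x)) == x` bit-for-bit.
#'
#' @param table a [count_table()].
#' @param path output file.
#' @param format `"tsv"` or `"biom"`.
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  m <- ct_matrix(table)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM requires the 'biomformat' package")
    biomformat::write_biom(biomformat::make_biom(t(m)), path)
    return(invisible(path))
  }
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects columns `sample_id`, `island_id` (empty/NA for controls),
#' `compartment` (detritus, water, invertebrate, negative_control), `locus`
#' (16S or 18S) and `replicate_index`.
#'
#' @param path TSV file.
#' @return a validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  df$replicate_index <- as.integer(df$replicate_index)
  df$island_id[df$island_id %in% c("", "NA")] <- NA_character_
  validate_sample_metadata(df)
}

validate_sample_metadata <- function(df) {
  need <- c("sample_id", "island_id", "compartment", "locus", "replicate_index")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample metadata missing column(s): ", id_list(miss))
  problems <- character(0)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) problems <- c(problems, paste0("duplicate sample ids: ", id_list(dup)))
  bad_c <- unique(df$sample_id[!df$compartment %in% COMPARTMENTS])
  if (length(bad_c))
    problems <- c(problems, paste0("unknown compartment for: ", id_list(bad_c)))
  bad_l <- unique(df$sample_id[!df$locus %in% LOCI])
  if (length(bad_l))
    problems <- c(problems, paste0("unknown locus for: ", id_list(bad_l)))
  bad_r <- df$sample_id[is.na(df$replicate_index) | df$replicate_index < 1L]
  if (length(bad_r))
    problems <- c(problems, paste0("replicate_index must be a positive integer for: ",
                                   id_list(bad_r)))
  no_isl <- df$sample_id[df$compartment != "negative_control" & is.na(df$island_id)]
  if (length(no_isl))
    problems <- c(problems, paste0("non-control samples without island_id: ",
                                   id_list(no_isl)))
  if (length(problems))
    stop("invalid sample metadata:\n  ", paste(problems, collapse = "\n  "))
  df
}

#' Read per-island metadata
#'
#' Island sizes (`water_volume_ml`, `detritus_weight_mg`) must be strictly
#' positive because they are log-transformed downstream; environmental
#' covariates may be NA and are handled complete-case per analysis.
#'
#' @param path TSV file.
#' @return a validated data.frame.
#' @export
read_island_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  validate_island_metadata(df)
}

validate_island_metadata <- function(df) {
  need <- c("island_id", "water_volume_ml", "detritus_weight_mg")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("island metadata missing column(s): ", id_list(miss))
  problems <- character(0)
  dup <- unique(df$island_id[duplicated(df$island_id)])
  if (length(dup)) problems <- c(problems, paste0("duplicate island ids: ", id_list(dup)))
  bad_w <- df$island_id[!is.finite(df$water_volume_ml) | df$water_volume_ml <= 0]
  if (length(bad_w))
    problems <- c(problems, paste0("non-positive water_volume_ml for: ", id_list(bad_w)))
  bad_d <- df$island_id[!is.finite(df$detritus_weight_mg) | df$detritus_weight_mg <= 0]
  if (length(bad_d))
    problems <- c(problems, paste0("non-positive detritus_weight_mg for: ", id_list(bad_d)))
  if ("complexity" %in% colnames(df)) {
    bad_k <- df$island_id[!is.na(df$complexity) & df$complexity < 1]
    if (length(bad_k))
      problems <- c(problems, paste0("complexity < 1 for: ", id_list(bad_k)))
  }
  if (length(problems))
    stop("invalid island metadata:\n  ", paste(problems, collapse = "\n  "))
  df
}

#' Bundle a count table with its sample and island metadata
#'
#' Every sample in the table must have a metadata row, and every non-control
#' sample must reference a known island (errors enumerate all offenders).
#' Metadata rows without a matching sample, and islands without samples, are
#' reported as warnings and kept.
#'
#' @param table a [count_table()].
#' @param samples sample metadata data.frame.
#' @param islands island metadata data.frame.
#' @return an object of class `sar_bundle`.
#' @export
join_metadata <- function(table, samples, islands) {
  samples <- validate_sample_metadata(samples)
  islands <- validate_island_metadata(islands)
  missing_meta <- setdiff(rownames(table), samples$sample_id)
  if (length(missing_meta))
    stop("samples in count table without metadata: ", id_list(missing_meta))
  noncontrol <- samples[samples$compartment != "negative_control", ]
  bad_isl <- unique(noncontrol$island_id[!noncontrol$island_id %in% islands$island_id])
  if (length(bad_isl))
    stop("samples reference unknown island(s): ", id_list(bad_isl))
  orphan_s <- setdiff(samples$sample_id, rownames(table))
  if (length(orphan_s))
    warning("metadata rows without samples in the count table: ", id_list(orphan_s))
  orphan_i <- setdiff(islands$island_id,
                      samples$island_id[!is.na(samples$island_id)])
  if (length(orphan_i))
    warning("islands without any samples: ", id_list(orphan_i))
  samples <- samples[match(rownames(table), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(table = table, samples = samples, islands = islands),
            class = "sar_bundle")
}

#' @export
print.sar_bundle <- function(x, ...) {
  cat(sprintf("sar_bundle: %d samples x %d ASVs over %d islands\n",
              nrow(x$table), ncol(x$table), nrow(x$islands)))
  print(table(x$samples$compartment, x$samples$locus))
  invisible(x)
}
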
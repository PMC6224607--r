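#' Flat key-value config files
#'
#' Minimal `key = value` text format used for parameter configs and truth
#' sidecar files: one pair per line, `#` starts a comment, values kept as
#' strings (callers coerce).
#'
#' @param x named list (or vector) of scalar values.
#' @param path file path.
#' @return `read_kv()` returns a named list of character values;
#'   `write_kv()` returns `path` invisibly.
#' @export
write_kv <- function(x, path) {
  stopifnot(length(names(x)) == length(x), all(nzchar(names(x))))
  lines <- vapply(seq_along(x), function(i)
    paste0(names(x)[i], " = ", format(x[[i]], digits = 17, scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kv
#' @export
read_kv <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- trimws(vapply(parts, `[`, character(1), 1))
  vals <- trimws(vapply(parts, `[`, character(1), 2))
  setNames(as.list(vals), keys)
}

#' Read and write clone-count tables
#'
#' Clone tables are tab-delimited UTF-8 text with header
#' `animal_id, genotype, time_weeks, n_basal, n_suprabasal`, one row per
#' scored clone.
#'
#' @param clones data frame with the columns above.
#' @param path file path.
#' @return `read_clone_table()` returns the validated data frame.
#' @export
write_clone_table <- function(clones, path) {
  clones <- validate_clone_table(clones)
  write.table(clones, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path) {
  validate_clone_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname write_clone_table
#' @export
validate_clone_table <- function(clones) {
  need <- c("animal_id", "genotype", "time_weeks", "n_basal", "n_suprabasal")
  miss <- setdiff(need, names(clones))
  if (length(miss)) stop("clone table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(clones$n_basal < 0) || any(clones$n_suprabasal < 0))
    stop("negative cell counts in clone table")
  if (any(clones$time_weeks < 0)) stop("negative times in clone table")
  clones[need]
}

#' Read and write variant tables
#'
#' Variant tables are tab-delimited text with columns
#' `chrom, pos, ref, alt, biopsy_id, mouse_id, exposure, p_value,
#' fwd_reads, rev_reads` (1-based positions, exposure one of
#' `irradiated`/`unexposed`).
#'
#' @param records variant data frame.
#' @param path file path.
#' @return `read_variant_table()` returns the validated data frame.
#' @export
write_variant_table <- function(records, path) {
  records <- validate_variant_table(records)
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  chr <- c(chrom = "character", ref = "character", alt = "character",
           biopsy_id = "character", mouse_id = "character",
           exposure = "character")   # "T" alleles must not parse as logical
  validate_variant_table(read.delim(path, stringsAsFactors = FALSE,
                                    colClasses = chr))
}

#' @rdname write_variant_table
#' @export
validate_variant_table <- function(records) {
  need <- c("chrom", "pos", "ref", "alt", "biopsy_id", "mouse_id",
            "exposure", "p_value", "fwd_reads", "rev_reads")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(records)) {
    if (any(records$ref == records$alt)) stop("ref == alt in variant table")
    bad <- !records$exposure %in% c("irradiated", "unexposed")
    if (any(bad)) stop("ambiguous exposure labels: ",
                       paste(unique(records$exposure[bad]), collapse = ", "))
  }
  records
}
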
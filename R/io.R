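#' Write variants to a minimal VCF file
#'
#' Emits a VCFv4.2 file with CHROM/POS/ID/REF/ALT and optional INFO
#' key=value fields.  Positions are written 1-based per the VCF
#' convention (internal coordinates are 0-based half-open only for
#' interval types such as BED windows; point variants are stored
#' 1-based throughout).
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   optionally `id`, `qual`, `filter`, and extra columns named in
#'   `info_fields` written as INFO tags.
#' @param path output file.
#' @param info_fields character vector of column names to serialize into
#'   INFO (numeric formatting is locale-independent).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, path, info_fields = character(0)) {
  v <- variants
  n <- nrow(v)
  info <- if (length(info_fields) == 0) rep(".", n) else {
    apply(v[, info_fields, drop = FALSE], 1, function(row)
      paste(paste0(info_fields, "=",
                   vapply(row, format, "", trim = TRUE, scientific = FALSE)),
            collapse = ";"))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonescope",
           vapply(info_fields, function(f) sprintf(
             "##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">", f, f), ""),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- paste(v$chrom, v$pos,
                v$id %||% rep(".", n), v$ref, v$alt,
                v$qual %||% rep(".", n), v$filter %||% rep(".", n),
                info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF file
#'
#' @param path VCF file (plain text).
#' @return data.frame with `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#'   `filter`, `info`, plus one column per INFO key found.  Parse errors
#'   report the offending line number.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) == 0)
    return(data.frame(chrom = character(0), pos = integer(0)))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8)
  if (length(bad))
    stop("malformed VCF record at line ", body_idx[bad[1]], " of ", path)
  m <- do.call(rbind, fields)
  out <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), id = m[, 3],
                    ref = m[, 4], alt = m[, 5], qual = m[, 6],
                    filter = m[, 7], info = m[, 8],
                    stringsAsFactors = FALSE)
  keys <- unique(unlist(lapply(strsplit(out$info[out$info != "."], ";"),
                               function(kv) sub("=.*", "", kv))))
  for (key in keys) {
    pat <- paste0("(?:^|;)", key, "=([^;]*)")
    mm <- regmatches(out$info, regexec(pat, out$info))
    out[[key]] <- vapply(mm, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  out
}

#' Write genomic intervals to BED (0-based half-open)
#' @param intervals data.frame with `chrom`, `start`, `end`, optional
#'   `name`, `score`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open preserved)
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`.
#' @export
read_bed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE,
                  colClasses = c(V1 = "character"))
  names(d) <- c("chrom", "start", "end", "name", "score")[seq_len(ncol(d))]
  d
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_file()]
#' @param path file.
#' @return data.frame.
#' @export
read_tsv_file <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Parse-then-rewrite round trip for a standard format
#'
#' Reads the file, rewrites it (to `out_path`), and returns the parsed
#' object; parsing the rewritten file yields a semantically identical
#' object, which is the property the pipeline relies on for all its
#' interchange formats.
#'
#' @param path input file.
#' @param format one of "vcf", "bed", "newick", "tsv", "json", "yaml";
#'   inferred from the extension when NULL.
#' @param out_path where to rewrite (default: overwrite in place).
#' @return the parsed object, invisibly.
#' @export
roundtrip_io <- function(path, format = NULL, out_path = path) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               vcf = "vcf", bed = "bed",
                               nwk = "newick", newick = "newick",
                               tre = "newick", tsv = "tsv", txt = "tsv",
                               json = "json", yaml = "yaml", yml = "yaml",
                               stop("cannot infer format of ", path))
  obj <- switch(format,
                vcf = read_vcf(path),
                bed = read_bed(path),
                newick = ape::read.tree(path),
                tsv = read_tsv_file(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = yaml::read_yaml(path),
                stop("unsupported format: ", format))
  switch(format,
         vcf = write_vcf(obj, out_path,
                         info_fields = setdiff(names(obj),
                                               c("chrom", "pos", "id", "ref",
                                                 "alt", "qual", "filter",
                                                 "info"))),
         bed = write_bed(obj, out_path),
         newick = ape::write.tree(obj, out_path),
         tsv = write_tsv_file(obj, out_path),
         json = jsonlite::write_json(obj, out_path, auto_unbox = TRUE,
                                     digits = NA, null = "null"),
         yaml = yaml::write_yaml(obj, out_path))
  invisible(obj)
}
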
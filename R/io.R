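#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased, whitespace is stripped, and RNA (U) is converted
#' to the canonical DNA alphabet (T). Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, possibly empty) and
#'   `sequence` (uppercase DNA over A,C,G,T,N).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">geneA first", "ATGAAA", ">geneB", "atguuu"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  header_idx <- grep("^>", lines)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  if (length(header_idx) == 0L || nonempty[1L] < header_idx[1L]) {
    stop("malformed FASTA: sequence before first header at line ",
         nonempty[1L], call. = FALSE)
  }
  ids <- character(length(header_idx))
  descs <- character(length(header_idx))
  seqs <- character(length(header_idx))
  bounds <- c(header_idx, length(lines) + 1L)
  for (i in seq_along(header_idx)) {
    header <- sub("^>", "", lines[header_idx[i]])
    if (!nzchar(trimws(header))) {
      stop("malformed FASTA: empty header at line ", header_idx[i],
           call. = FALSE)
    }
    toks <- strsplit(trimws(header), "\\s+")[[1L]]
    ids[i] <- toks[1L]
    descs[i] <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else ""
    body <- lines[seq(header_idx[i] + 1L, bounds[i + 1L] - 1L)]
    if (bounds[i + 1L] - 1L < header_idx[i] + 1L) body <- character(0)
    seq <- gsub("\\s", "", paste(body, collapse = ""))
    ## validate with the offending line number for usable error messages
    seq_canon <- tryCatch(canonical_dna(seq, what = paste0("record '", ids[i], "'")),
      error = function(e) {
        for (ln in seq(header_idx[i] + 1L, bounds[i + 1L] - 1L)) {
          bad <- gsub("[ACGTUNacgtun \t]", "", lines[ln])
          if (nchar(bad) > 0L) {
            stop("illegal character '", substr(bad, 1L, 1L),
                 "' in FASTA record '", ids[i], "' at line ", ln,
                 call. = FALSE)
          }
        }
        stop(conditionMessage(e), call. = FALSE)
      })
    if (!nzchar(seq_canon)) {
      stop("FASTA record '", ids[i], "' (line ", header_idx[i],
           ") has an empty sequence", call. = FALSE)
    }
    seqs[i] <- seq_canon
  }
  data.frame(id = ids, description = descs, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records)) records$description[i] else ""
    header <- if (nzchar(desc)) paste(records$id[i], desc) else records$id[i]
    writeLines(paste0(">", header), con)
    seq <- records$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  invisible(path)
}

#' Construct a transcript model (CDS + 3'UTR)
#'
#' @param gene_id gene identifier.
#' @param cds coding sequence; length must be divisible by 3.
#' @param utr3 3' untranslated region (may be empty).
#' @param complete if `TRUE`, the CDS is validated as a complete ORF: it must
#'   begin with ATG and contain no internal stop codon (a terminal stop is
#'   allowed).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, cds, utr3 = "", complete = FALSE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  cds <- canonical_dna(cds, "CDS")
  utr3 <- if (nzchar(utr3)) canonical_dna(utr3, "3'UTR") else ""
  if (nchar(cds) == 0L) stop("CDS is empty", call. = FALSE)
  codons <- split_codons(cds)
  if (isTRUE(complete)) {
    if (codons[1L] != "ATG") {
      stop("complete CDS must begin with ATG, got ", codons[1L], call. = FALSE)
    }
    gc <- genetic_code()
    internal <- codons[-length(codons)]
    stops <- internal[internal %in% names(gc)[gc == "*"]]
    if (length(stops) > 0L) {
      stop("complete CDS contains internal stop codon ", stops[1L],
           call. = FALSE)
    }
  }
  structure(list(gene_id = gene_id, cds = cds, utr3 = utr3,
                 complete = isTRUE(complete)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript model:", x$gene_id, "\n")
  cat("  CDS:", nchar(x$cds), "nt (", nchar(x$cds) %/% 3L, "codons )\n")
  cat("  3'UTR:", nchar(x$utr3), "nt\n")
  invisible(x)
}

#' Read a typed tab- or comma-separated table with schema validation
#'
#' @param path path to a delimited file with a header row.
#' @param schema named character vector mapping required column names to types
#'   (`"character"`, `"numeric"`, `"integer"`). Extra columns are kept
#'   untouched.
#' @param sep field separator; defaults to tab.
#' @return data.frame with validated, typed columns. Missing values remain
#'   `NA` and are reported via the `n_missing` attribute, never dropped.
#' @export
read_table <- function(path, schema, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    raw <- df[[col]]
    raw[raw == ""] <- NA_character_
    if (type %in% c("numeric", "integer")) {
      parsed <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(parsed))
      if (length(bad) > 0L) {
        stop("column '", col, "' has non-numeric value '", raw[bad[1L]],
             "' at data row ", bad[1L], call. = FALSE)
      }
      df[[col]] <- if (type == "integer") as.integer(round(parsed)) else parsed
    } else {
      df[[col]] <- raw
    }
  }
  attr(df, "n_missing") <- vapply(df[names(schema)],
                                  function(x) sum(is.na(x)), integer(1))
  df
}

#' Write a tabular report as TSV
#'
#' Floats are written at a fixed precision and rows are sorted on the given
#' keys so repeated runs produce byte-identical, diffable files. Coordinates
#' in all reports are 1-based inclusive.
#'
#' @param dataset data.frame to write.
#' @param path output path.
#' @param digits number of significant decimal places for numeric columns.
#' @param sort_by character vector of column names to order rows by; `NULL`
#'   keeps input order.
#' @param allow_empty allow writing a header-only file for a 0-row dataset.
#' @return invisibly, `path`.
#' @export
write_report <- function(dataset, path, digits = 4L, sort_by = NULL,
                         allow_empty = FALSE) {
  stopifnot(is.data.frame(dataset))
  if (nrow(dataset) == 0L && !allow_empty) {
    stop("refusing to write an empty report (set allow_empty = TRUE)",
         call. = FALSE)
  }
  if (!is.null(sort_by)) {
    missing_keys <- setdiff(sort_by, names(dataset))
    if (length(missing_keys) > 0L) {
      stop("sort_by column(s) not in dataset: ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    }
    dataset <- dataset[do.call(order, dataset[sort_by]), , drop = FALSE]
  }
  out <- dataset
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = digits,
                                                   format = "f"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
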
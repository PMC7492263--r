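# File readers/writers for every format the pipeline touches.

#' Read protein sequences from FASTA
#'
#' Parses a protein FASTA file into a data frame of records. The first
#' whitespace-delimited token of each header is taken as the locus ID
#' (RGAP style, e.g. `LOC_Os05g22970`); sequences are uppercased and must
#' use the 20 standard amino-acid letters plus X.
#'
#' @param path FASTA file.
#' @return data frame with columns `locus_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(lines[nonblank[1]], ">"))
    stop(sprintf("malformed FASTA in %s: sequence before any header at line %d",
                 path, nonblank[1]))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    return(data.frame(locus_id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate locus_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(unname(as.character(aa)))
  for (i in seq_along(seqs)) validate_sequence(seqs[i], ids[i])
  data.frame(locus_id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data frame with `locus_id` and `sequence` columns.
#' @param path output file; sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence,
                                                 records$locus_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a normalized predictor score table
#'
#' Long-format TSV with header columns `protein_id`, `tool`, `compartment`,
#' `score` — the common carrier for WoLF-PSORT / YLoc / CELLO compartment
#' scores and NucPred scores (for NucPred the compartment column holds
#' `"nuclear"` and the score is the NucPred score itself).
#'
#' @param path TSV file.
#' @return data frame with the four columns, scores numeric.
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "tool", "compartment", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("prediction table missing column(s): ", paste(miss, collapse = ", "))
  df$tool <- tolower(df$tool)
  bad <- setdiff(unique(df$tool), TOOLS)
  if (length(bad))
    stop("unknown tool name(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(TOOLS, collapse = ", "), ")")
  if (!is.numeric(df$score)) {
    sc <- suppressWarnings(as.numeric(df$score))
    if (anyNA(sc) & !anyNA(df$score))
      stop("non-numeric score in prediction table")
    df$score <- sc
  }
  if (anyNA(df$score)) stop("non-numeric or missing score in prediction table")
  df[need]
}

#' Read per-residue NES score tracks
#'
#' TSV with columns `protein_id`, `position` (1-based), `residue`, `score`,
#' as produced by NetNES-style predictors. Positions absent from the file
#' default to score 0; when `records` is supplied, each track is padded to
#' the protein's sequence length and residue letters are cross-checked
#' against the sequence (a mismatch logs a warning; the sequence wins).
#'
#' @param path TSV file; an empty file yields an empty mapping.
#' @param records optional data frame from [read_fasta()].
#' @return named list of numeric per-residue score vectors.
#' @export
read_residue_scores <- function(path, records = NULL) {
  first <- readLines(path, n = 2L, warn = FALSE)
  if (length(first) == 0L) return(stats::setNames(list(), character()))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("residue score table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(stats::setNames(list(), character()))
  if (any(df$position < 1))
    stop("residue score positions must be >= 1 (1-based)")
  seqs <- if (is.null(records)) NULL else
    stats::setNames(records$sequence, records$locus_id)
  out <- lapply(split(df, df$protein_id), function(d) {
    len <- max(d$position)
    if (!is.null(seqs) && d$protein_id[1] %in% names(seqs)) {
      sq <- seqs[[d$protein_id[1]]]
      if (len > nchar(sq))
        stop("residue score position beyond sequence length for ",
             d$protein_id[1])
      len <- nchar(sq)
      obs <- substring(sq, d$position, d$position)
      if (any(obs != toupper(d$residue)))
        warning(sum(obs != toupper(d$residue)),
                " residue mismatch(es) vs sequence for ", d$protein_id[1],
                "; sequence wins", call. = FALSE)
    }
    track <- numeric(len)
    track[d$position] <- d$score
    track
  })
  out[unique(df$protein_id)]
}

#' Read a localization-evidence table
#'
#' RFC-4180 CSV with columns `protein_id`, `source` (PMID or experiment
#' tag), `cell_system`, `compartments` (semicolon-separated lowercase
#' tokens, e.g. `"nucleus;cytoplasm"`). Records with an empty compartment
#' set are rejected with a logged reason.
#'
#' @param path CSV file.
#' @return data frame with the original columns plus logical `nuclear`
#'   (`"nucleus"` among the compartments) and `nucleus_only`.
#' @export
read_evidence_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "source", "cell_system", "compartments")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("evidence table missing column(s): ", paste(miss, collapse = ", "))
  toks <- lapply(strsplit(tolower(as.character(df$compartments)), ";",
                          fixed = TRUE),
                 function(t) { t <- trimws(t); unique(t[nzchar(t)]) })
  empty <- lengths(toks) == 0L
  if (any(empty)) {
    message(sum(empty), " evidence record(s) rejected: empty compartment set (",
            paste(utils::head(df$protein_id[empty], 5), collapse = ", "), ")")
    df <- df[!empty, , drop = FALSE]
    toks <- toks[!empty]
  }
  df$compartments <- vapply(toks, paste, "", collapse = ";")
  df$nuclear <- vapply(toks, function(t) "nucleus" %in% t, logical(1))
  df$nucleus_only <- vapply(toks, function(t) identical(t, "nucleus"), logical(1))
  rownames(df) <- NULL
  df
}

#' Read GO and transcription-factor annotation tables
#'
#' @param go_path TSV with columns `locus_id`, `go_id` (one pair per row),
#'   or `NULL`.
#' @param tf_path TSV with columns `locus_id`, `family`, or `NULL`.
#' @return list with elements `go` and `tf` (data frames or `NULL`).
#' @export
read_annotation_tables <- function(go_path = NULL, tf_path = NULL) {
  read_two <- function(path, cols) {
    if (is.null(path)) return(NULL)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("annotation table ", path, " missing column(s): ",
           paste(miss, collapse = ", "))
    df[cols]
  }
  list(go = read_two(go_path, c("locus_id", "go_id")),
       tf = read_two(tf_path, c("locus_id", "family")))
}

#' Read a splice-variant grouping table
#'
#' @param path TSV with columns `gene_id`, `variant_id`.
#' @return data frame mapping genes to their splice variants.
#' @export
read_splice_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "variant_id"), names(df))
  if (length(miss))
    stop("splice table missing column(s): ", paste(miss, collapse = ", "))
  df[c("gene_id", "variant_id")]
}
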
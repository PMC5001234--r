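#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()]: records are returned in
#' file order, upper-cased; validation against the solver's alphabet is
#' deferred to [ems_solve()].
#'
#' @param path Path to a FASTA file (multi-line records allowed).
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read FASTA file '%s'", path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (!length(set)) {
    stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  }
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write a motif list to a plain-text file
#'
#' One motif per line in lexicographic order, preceded by `#` header
#' comments recording the run metadata, with a trailing newline.
#'
#' @param motifs Sorted character vector of motifs.
#' @param path Output path.
#' @param meta Named list written as `# name: value` header lines
#'   (typically `l`, `d`, `n`, `engine`, `seed`).
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path, meta = list()) {
  meta <- c(list(count = length(motifs)), meta)
  header <- sprintf("# %s: %s", names(meta),
                    vapply(meta, function(v) paste(format(v), collapse = " "),
                           character(1)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, motifs), con)
  invisible(path)
}

#' Read a motif list written by [write_motifs()]
#'
#' @param path Path to a motif list file.
#' @return Character vector of motifs (header comments dropped).
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Write an instance to a FASTA file
#'
#' Sequences go out as FASTA records; when the instance carries a planted
#' motif, the motif and per-string plant positions are recorded in `;`
#' comment lines before the first record (FASTA comments, ignored by
#' readers).
#'
#' @param instance An `ems_instance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instance_fasta <- function(instance, path) {
  stopifnot(inherits(instance, "ems_instance"))
  lines <- character()
  if (!is.null(instance$planted)) {
    lines <- c(
      sprintf("; planted_motif %s", instance$planted$motif),
      sprintf("; plant_positions %s",
              paste(instance$planted$positions, collapse = " "))
    )
  }
  ids <- sprintf("seq%0*d", nchar(length(instance$sequences)),
                 seq_along(instance$sequences))
  body <- as.vector(rbind(paste0(">", ids), instance$sequences))
  writeLines(c(lines, body), path)
  invisible(path)
}
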
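#' ITS record collections
#'
#' An ITS record collection is a data frame with columns `id` (unique),
#' `group_label` (optional lineage/group tag, NA when unknown) and
#' `sequence` (A/C/G/T/N). 16S-23S ITS sequences are the high-resolution
#' marker used to separate closely related genotypes within a genus.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of nucleotide sequences.
#' @param group_label Optional character vector of group tags.
#' @return Validated data frame of class `its_records`.
#' @export
its_records <- function(id, sequence, group_label = NA_character_) {
  df <- data.frame(id = as.character(id),
                   group_label = as.character(group_label),
                   sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  validate_its_records(df)
}

#' @rdname its_records
#' @param records Candidate record data frame.
#' @export
validate_its_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (is.null(records$group_label)) records$group_label <- NA_character_
  if (anyDuplicated(records$id)) {
    stop("duplicate record ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    assert_iupac(records$sequence[i], sprintf("record '%s'", records$id[i]),
                 strict = TRUE)
  }
  class(records) <- c("its_records", "data.frame")
  records
}

#' Read ITS records from FASTA
#'
#' Headers of the form `id group=LABEL` populate `group_label`; anything
#' else after the id is ignored.
#'
#' @param path FASTA file path.
#' @return An `its_records` data frame.
#' @export
read_its_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  groups <- ifelse(grepl("group=", headers),
                   sub(".*group=([^ ]+).*", "\\1", headers), NA_character_)
  its_records(id = ids, sequence = toupper(as.character(set)),
              group_label = groups)
}

#' Write ITS records to FASTA (wrapped at 60 columns)
#'
#' @param records An `its_records` collection.
#' @param path Output path.
#' @export
write_its_fasta <- function(records, path) {
  records <- validate_its_records(records)
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- ifelse(is.na(records$group_label), records$id,
                       paste0(records$id, " group=", records$group_label))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
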
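#' Read a PED/FAM-style pedigree file
#'
#' Reads a tab-separated genealogy file with six columns: `pedigree_id`,
#' `individual_id`, `father_id`, `mother_id`, `sex` (1 = male, 2 = female,
#' 0 = unknown) and `sampled` (0/1). A header line is optional and is
#' detected by a non-numeric entry in the sex column. `"0"` and the empty
#' string in the parent columns mean "no recorded parent" (FAM convention);
#' ids are case-sensitive opaque strings.
#'
#' @param path file path.
#' @param founders optional named list: for each pedigree id, a character
#'   vector of founder individual ids (otherwise founders are inferred; see
#'   [pedigree()]).
#' @return named list of `"pedigree"` objects, one per pedigree id.
#' @seealso [write_ped()]
#' @export
read_ped <- function(path, founders = NULL) {
  first <- utils::read.table(path, sep = "\t", colClasses = "character",
                             nrows = 1, header = FALSE)
  if (ncol(first) < 6) stopf("read_ped: expected 6 tab-separated columns")
  has_header <- !(first[[5]] %in% c("0", "1", "2"))
  df <- utils::read.table(path, sep = "\t", colClasses = "character",
                          header = has_header)
  names(df) <- c("pedigree_id", "individual_id", "father_id", "mother_id",
                 "sex", "sampled")[seq_len(ncol(df))]
  df$sex <- as.integer(df$sex)
  df$sampled <- as.integer(df$sampled)
  out <- lapply(split(df, factor(df$pedigree_id, levels = unique(df$pedigree_id))),
                function(sub) pedigree(sub, founders = founders[[sub$pedigree_id[1]]]))
  out
}

#' Write pedigrees to a PED/FAM-style file
#'
#' @param peds a `"pedigree"` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- lapply(peds, function(p) {
    data.frame(
      pedigree_id = p$pedigree_id,
      individual_id = p$id,
      father_id = ifelse(is.na(p$father), "0", p$id[p$father]),
      mother_id = ifelse(is.na(p$mother), "0", p$id[p$mother]),
      sex = c(male = 1L, female = 2L, unknown = 0L)[as.character(p$sex)],
      sampled = as.integer(p$sampled),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
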
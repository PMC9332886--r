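# Activity-record curation: EC50 -> pEC50, duplicate/salt/imprecise
# filtering, and train/prediction splitting.

#' Convert EC50 to pEC50
#'
#' pEC50 = -log10 of the molar EC50. Values in nM or uM are converted to
#' molar first.
#'
#' @param ec50 positive numeric vector.
#' @param unit `"nM"`, `"uM"` or `"M"`.
#' @return numeric vector of pEC50 values.
#' @export
#' @examples
#' to_pec50(0.38, "nM")   # 9.42: a sub-nanomolar inhibitor
#' to_pec50(1, "M")       # 0
to_pec50 <- function(ec50, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ec50)) || any(ec50 <= 0))
    stop("EC50 values must be positive and finite")
  factor <- c(nM = 1e-9, uM = 1e-6, M = 1)[[unit]]
  -log10(ec50 * factor)
}

#' Inverse of [to_pec50()]
#' @param pec50 numeric vector.
#' @param unit output unit.
#' @return EC50 in the requested unit.
#' @export
from_pec50 <- function(pec50, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  factor <- c(nM = 1e-9, uM = 1e-6, M = 1)[[unit]]
  10^(-pec50) / factor
}

#' Read an activity table
#'
#' CSV with columns `compound_id`, `smiles`, and `ec50_nM` and/or `pec50`;
#' optional `qualifier` (`=`, `>`, `<`, `~`; empty means `=`).
#'
#' The `smiles` column may be omitted when activities accompany a
#' precomputed descriptor matrix.
#'
#' @param path CSV file.
#' @param unit unit of the `ec50_nM` column (kept as `ec50_nM` regardless).
#' @return data frame of activity records.
#' @export
read_activity_csv <- function(path, unit = "nM") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("compound_id" %in% names(df)))
    stop("activity CSV must have a 'compound_id' column")
  if (!("ec50_nM" %in% names(df)) && !("pec50" %in% names(df)))
    stop("activity CSV needs an 'ec50_nM' or 'pec50' column")
  if (is.null(df$qualifier)) df$qualifier <- "="
  df$qualifier[is.na(df$qualifier) | df$qualifier == ""] <- "="
  if (is.null(df$pec50)) df$pec50 <- NA_real_
  if (is.null(df$ec50_nM)) df$ec50_nM <- NA_real_
  miss <- is.na(df$pec50) & !is.na(df$ec50_nM)
  df$pec50[miss] <- to_pec50(df$ec50_nM[miss], unit)
  df
}

#' Curate activity records
#'
#' Flags each record as kept or as exactly one of: `unparsable` (SMILES
#' rejected by the structure parser), `multi_component` (disconnected
#' structure: salt or mixture), `imprecise` (activity qualifier other than
#' `=`), or `duplicate` (same canonical structure key as an earlier kept
#' record; the first occurrence, in input order, is kept). Flag precedence
#' follows that order.
#'
#' @param records data frame as returned by [read_activity_csv()].
#' @param ignore_stereo treat stereoisomers as duplicates (default TRUE).
#' @return the records with columns `curation_flag`, `canonical_smiles`,
#'   and `kept`; the curation report (counts per flag) is attached as
#'   attribute `"report"`.
#' @export
curate <- function(records, ignore_stereo = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (is.null(records$smiles)) stop("curation needs a 'smiles' column")
  keys <- canonical_key(records$smiles, ignore_stereo = ignore_stereo)
  flag <- rep("kept", nrow(records))
  flag[is.na(keys)] <- "unparsable"
  flag[flag == "kept" & grepl(".", keys, fixed = TRUE)] <- "multi_component"
  flag[flag == "kept" & records$qualifier != "="] <- "imprecise"
  seen <- character()
  for (i in which(flag == "kept")) {
    if (keys[i] %in% seen) flag[i] <- "duplicate" else seen <- c(seen, keys[i])
  }
  records$canonical_smiles <- keys
  records$curation_flag <- flag
  records$kept <- flag == "kept"
  report <- as.list(table(factor(
    flag, levels = c("kept", "duplicate", "multi_component", "imprecise",
                     "unparsable"))))
  attr(records, "report") <- report
  records
}

#' Split compounds into training and prediction sets
#'
#' Simple random split without replacement under a recorded seed. The
#' training share is `floor(fraction * n)`, matching the convention that an
#' 80% split of 84 compounds gives 67 training and 17 prediction compounds.
#'
#' @param ids compound identifiers (or a single integer n, expanded to
#'   `1:n`).
#' @param fraction training share in (0, 1).
#' @param seed integer seed; the partition is reproducible under it.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_dataset <- function(ids, fraction = 0.8, seed = 1L) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- seq_len(ids)
  n <- length(ids)
  if (n < 5L) stop("refusing to split fewer than 5 compounds")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_train <- floor(fraction * n)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  tr <- sort(sample.int(n, n_train))
  list(train = ids[tr], test = ids[-tr], seed = seed, fraction = fraction)
}

# Save/restore the RNG state so seeded helpers do not perturb the caller.
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Write curated records and their curation report
#'
#' @param records output of [curate()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_curation <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, file.path(dir, "curated.csv"), row.names = FALSE)
  jsonlite::write_json(attr(records, "report"),
                       file.path(dir, "curation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
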
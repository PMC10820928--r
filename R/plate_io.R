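# Well-level data model, CSV I/O, and phenotype-vocabulary harmonization.

WELL_COLUMNS <- c("lab_id", "plate_id", "week_id", "well_id", "substance_id",
                  "role", "conc_uM", "dead_24", "dead_120", "phenotypes")
WELL_ROLES <- c("test", "vehicle", "positive")

#' Construct a study dataset
#'
#' Bundles well-level records with a phenotype vocabulary and optional
#' per-lab protocol metadata, and validates the invariants of the design:
#' one embryo per well, mortality monotone in time (an embryo dead at
#' 24 hpf is dead at 120 hpf), vehicle wells at concentration zero, unique
#' well identity within a plate, and at least one vehicle well on every
#' plate that carries test wells.
#'
#' @param wells data.frame with columns `lab_id`, `plate_id`, `week_id`,
#'   `well_id`, `substance_id`, `role` (one of `"test"`, `"vehicle"`,
#'   `"positive"`), `conc_uM`, `dead_24`, `dead_120` (logical), and
#'   `phenotypes` (semicolon-separated lab terms, empty string if none).
#' @param vocabulary data.frame with columns `lab_id`, `lab_term`,
#'   `harmonized_class`; see [default_vocabulary()].
#' @param metadata optional data.frame of per-lab protocol descriptors
#'   (e.g. chorion status, exposure regimen, strain).
#' @param strict logical; in strict mode, phenotypes recorded on dead
#'   embryos and broken endpoint nesting raise errors instead of warnings.
#' @return An object of class `study_dataset`: a list with elements
#'   `wells`, `vocabulary`, `metadata`, `strict`.
#' @export
study_dataset <- function(wells, vocabulary = default_vocabulary(),
                          metadata = NULL, strict = FALSE) {
  missing_cols <- setdiff(WELL_COLUMNS, names(wells))
  if (length(missing_cols) > 0L) {
    .stopf("well table is missing required column(s): %s",
           paste(missing_cols, collapse = ", "))
  }
  wells <- wells[, union(WELL_COLUMNS, names(wells))]
  for (col in c("lab_id", "plate_id", "week_id", "well_id", "substance_id", "role")) {
    wells[[col]] <- as.character(wells[[col]])
  }
  wells$conc_uM <- as.numeric(wells$conc_uM)
  wells$dead_24 <- .as_flag(wells$dead_24, "dead_24")
  wells$dead_120 <- .as_flag(wells$dead_120, "dead_120")
  wells$phenotypes <- ifelse(is.na(wells$phenotypes), "",
                             as.character(wells$phenotypes))

  bad_role <- !wells$role %in% WELL_ROLES
  if (any(bad_role)) {
    .stopf("unknown role value(s): %s",
           paste(unique(wells$role[bad_role]), collapse = ", "))
  }
  if (any(is.na(wells$conc_uM) | wells$conc_uM < 0)) {
    .stopf("conc_uM must be non-negative and non-missing")
  }
  bad_veh <- wells$role == "vehicle" & wells$conc_uM != 0
  if (any(bad_veh)) {
    .stopf("vehicle wells must have conc_uM = 0 (e.g. well %s on plate %s)",
           wells$well_id[bad_veh][1L], wells$plate_id[bad_veh][1L])
  }
  bad_mort <- wells$dead_24 & !wells$dead_120
  if (any(bad_mort)) {
    .stopf(
      "mortality must be monotone in time: well %s on plate %s (lab %s) is dead at 24 hpf but alive at 120 hpf",
      wells$well_id[bad_mort][1L], wells$plate_id[bad_mort][1L],
      wells$lab_id[bad_mort][1L])
  }
  key <- paste(wells$lab_id, wells$plate_id, wells$well_id, sep = "\r")
  if (anyDuplicated(key)) {
    .stopf("duplicated (lab_id, plate_id, well_id): %s",
           gsub("\r", "/", key[duplicated(key)][1L]))
  }
  # phenotypes are scored in viable embryos only
  dead_pheno <- wells$dead_120 & nzchar(wells$phenotypes)
  if (any(dead_pheno)) {
    if (strict) {
      .stopf("phenotypes recorded on %d dead embryo(s); first: well %s plate %s",
             sum(dead_pheno), wells$well_id[dead_pheno][1L],
             wells$plate_id[dead_pheno][1L])
    }
    .warnf("dropping phenotypes recorded on %d dead embryo(s); alterations are scored in viable embryos only",
           sum(dead_pheno))
    wells$phenotypes[dead_pheno] <- ""
  }
  # every plate with test wells carries >= 1 vehicle well
  plates_test <- unique(paste(wells$lab_id, wells$plate_id, sep = "\r")[wells$role == "test"])
  plates_veh <- unique(paste(wells$lab_id, wells$plate_id, sep = "\r")[wells$role == "vehicle"])
  orphan <- setdiff(plates_test, plates_veh)
  if (length(orphan) > 0L) {
    .stopf("plate(s) with test wells but no vehicle control: %s",
           paste(gsub("\r", "/", orphan), collapse = ", "))
  }
  rownames(wells) <- NULL
  structure(list(wells = wells, vocabulary = vocabulary,
                 metadata = metadata, strict = strict),
            class = "study_dataset")
}

.as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- as.integer(x)
  if (any(is.na(x) | !x %in% c(0L, 1L))) {
    .stopf("column %s must be 0/1 or logical", what)
  }
  x == 1L
}

#' @export
print.study_dataset <- function(x, ...) {
  w <- x$wells
  cat(sprintf("study_dataset: %d wells, %d labs, %d plates, %d substances\n",
              nrow(w), length(unique(w$lab_id)),
              nrow(unique(w[, c("lab_id", "plate_id")])),
              length(unique(w$substance_id[w$role == "test"]))))
  invisible(x)
}

#' Default phenotype vocabulary
#'
#' Flat mapping from lab-specific phenotype terms (as recorded by three
#' screening laboratories with different in-house scoring systems) to six
#' harmonized classes: edema, craniofacial, axis, trunk, pigment, other.
#' Terms that do not describe a structural malformation class (delayed
#' hatching, unhatched, yolk opacity, necrosis, catch-all "Others") map to
#' `other`.
#'
#' @return data.frame with columns `lab_id`, `lab_term`, `harmonized_class`.
#' @export
#' @examples
#' head(default_vocabulary())
default_vocabulary <- function() {
  path <- system.file("extdata", "phenotype_vocabulary.csv",
                      package = "bmcscreen", mustWork = TRUE)
  read_vocabulary(path)
}

#' Read a phenotype vocabulary CSV
#'
#' @param path CSV with columns `lab_id`, `lab_term`, `harmonized_class`.
#' @return data.frame vocabulary.
#' @export
read_vocabulary <- function(path) {
  v <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("lab_id", "lab_term", "harmonized_class")
  missing_cols <- setdiff(need, names(v))
  if (length(missing_cols) > 0L) {
    .stopf("vocabulary is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  bad <- !v$harmonized_class %in% phenotype_classes()
  if (any(bad)) {
    .stopf("unknown harmonized class(es): %s",
           paste(unique(v$harmonized_class[bad]), collapse = ", "))
  }
  v
}

# Normalised lookup key: vocabulary matching ignores case and surrounding
# whitespace, since lab reports are hand-typed.
.term_key <- function(lab_id, term) paste(lab_id, tolower(trimws(term)), sep = "\r")

#' Map lab-specific phenotype terms to harmonized classes
#'
#' Adds a `harmonized` column to the well table: the set (semicolon-joined,
#' deduplicated, sorted) of harmonized classes the well's recorded
#' phenotype terms map onto. Idempotent; in lenient mode unmapped terms are
#' routed to class `other` with a warning, in strict mode they are an error.
#'
#' @param dataset a [study_dataset()].
#' @param strict logical; overrides the dataset's strict flag if given.
#' @return The dataset with `wells$harmonized` filled in.
#' @export
map_phenotypes <- function(dataset, strict = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.null(strict)) strict <- isTRUE(dataset$strict)
  v <- dataset$vocabulary
  if (is.null(v)) .stopf("dataset has no phenotype vocabulary")
  lut <- setNames(v$harmonized_class, .term_key(v$lab_id, v$lab_term))
  w <- dataset$wells
  unmapped <- character(0)
  mapped <- character(nrow(w))
  for (i in seq_len(nrow(w))) {
    if (!nzchar(w$phenotypes[i])) { mapped[i] <- ""; next }
    terms <- trimws(strsplit(w$phenotypes[i], ";", fixed = TRUE)[[1L]])
    terms <- terms[nzchar(terms)]
    cls <- unname(lut[.term_key(w$lab_id[i], terms)])
    miss <- is.na(cls)
    if (any(miss)) {
      unmapped <- c(unmapped, paste0(w$lab_id[i], ": ", terms[miss]))
      cls[miss] <- "other"
    }
    mapped[i] <- paste(sort(unique(cls)), collapse = ";")
  }
  if (length(unmapped) > 0L) {
    unmapped <- sort(unique(unmapped))
    if (strict) {
      .stopf("unmapped phenotype term(s): %s", paste(unmapped, collapse = "; "))
    }
    .warnf("%d unmapped phenotype term(s) routed to class 'other': %s",
           length(unmapped), paste(unmapped, collapse = "; "))
  }
  dataset$wells$harmonized <- mapped
  dataset
}

#' Read a well-level screening table
#'
#' Reads the long-format CSV interchange schema (one row per well) and
#' returns a validated [study_dataset()]. Phenotype cells are
#' semicolon-separated lists of lab terms, possibly empty.
#'
#' @param path CSV path.
#' @inheritParams study_dataset
#' @return A `study_dataset`.
#' @export
read_well_table <- function(path, vocabulary = default_vocabulary(),
                            strict = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  missing_cols <- setdiff(WELL_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    .stopf("%s is missing required column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  }
  raw$conc_uM <- as.numeric(raw$conc_uM)
  raw$dead_24 <- as.integer(raw$dead_24)
  raw$dead_120 <- as.integer(raw$dead_120)
  study_dataset(raw, vocabulary = vocabulary, strict = strict)
}

#' Write a well-level screening table
#'
#' Inverse of [read_well_table()]: writes the canonical columns as CSV so
#' that reading the file back reproduces the dataset field-for-field.
#'
#' @param dataset a [study_dataset()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_well_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  w <- dataset$wells[, WELL_COLUMNS]
  w$dead_24 <- as.integer(w$dead_24)
  w$dead_120 <- as.integer(w$dead_120)
  # 17 significant digits round-trip a double exactly through text
  w$conc_uM <- formatC(w$conc_uM, digits = 17, format = "g")
  write.csv(w, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
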
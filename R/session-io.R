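session_csv_header <- c("participant_id", "condition", "structure", "block",
                        "trial", "phase", "question", "dim1", "dim2",
                        "true_category", "response", "implied_category",
                        "correct", "feedback_given")

#' Read and write session logs as CSV
#'
#' One row per trial, comma-separated, header
#' `participant_id,condition,structure,block,trial,phase,question,dim1,dim2,true_category,response,implied_category,correct,feedback_given`.
#' Questions are encoded `A|B` (pair) or `is:A` (target); unanswered trials
#' carry response `none` and empty implied/correct fields. Coordinates are
#' written with 17 significant digits so `read_session_csv(write_session_csv(s))`
#' reproduces the session exactly. Reading validates the protocol
#' invariants via [validate_session()].
#'
#' @param session A `catrep_session`.
#' @param path File path.
#' @return `write_session_csv` returns `path` invisibly; `read_session_csv`
#'   returns a `catrep_session`.
#' @export
write_session_csv <- function(session, path) {
  validate_session(session)
  tr <- session$trials
  rows <- sprintf(
    "%s,%s,%s,%d,%d,%s,%s,%.17g,%.17g,%s,%s,%s,%s,%d",
    session$participant_id, session$condition, session$structure_kind,
    tr$block, tr$trial, tr$phase, tr$question, tr$dim1, tr$dim2,
    tr$true_category, tr$response,
    ifelse(is.na(tr$implied_category), "", tr$implied_category),
    ifelse(is.na(tr$correct), "", as.character(tr$correct)),
    tr$feedback_given
  )
  writeLines(c(paste(session_csv_header, collapse = ","), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L ||
      !identical(lines[1], paste(session_csv_header, collapse = ","))) {
    stop("parse error at line 1: unexpected header.", call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  # implied/correct may be empty but the trailing field never is, so every
  # well-formed row splits into exactly 14 fields
  bad <- which(n_fields != length(session_csv_header))
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d: expected %d fields, found %d.",
                 bad[1] + 1L, length(session_csv_header), n_fields[bad[1]]),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  colnames(m) <- session_csv_header
  pid <- unique(m[, "participant_id"])
  cond <- unique(m[, "condition"])
  kind <- unique(m[, "structure"])
  if (length(pid) != 1L || length(cond) != 1L || length(kind) != 1L) {
    stop("session CSV mixes participants, conditions, or structures.",
         call. = FALSE)
  }
  trials <- data.frame(
    trial = as.integer(m[, "trial"]),
    block = as.integer(m[, "block"]),
    phase = m[, "phase"],
    question = m[, "question"],
    dim1 = as.numeric(m[, "dim1"]),
    dim2 = as.numeric(m[, "dim2"]),
    true_category = m[, "true_category"],
    response = m[, "response"],
    implied_category = ifelse(m[, "implied_category"] == "", NA_character_,
                              m[, "implied_category"]),
    correct = suppressWarnings(as.integer(ifelse(m[, "correct"] == "", NA,
                                                 m[, "correct"]))),
    feedback_given = as.integer(m[, "feedback_given"]),
    stringsAsFactors = FALSE
  )
  trials <- trials[order(trials$trial), , drop = FALSE]
  rownames(trials) <- NULL
  session <- structure(
    list(participant_id = pid, condition = cond, structure_kind = kind,
         seed = NA_integer_, trials = trials, agent = NULL),
    class = "catrep_session"
  )
  validate_session(session)
  session
}

#' Read and write cohorts as a directory of session CSVs plus a manifest
#'
#' The manifest (`manifest.json`) records, per participant: id, file name,
#' condition, structure, schedule seed and -- for simulated cohorts -- the
#' generating agent configuration (its true representation tag is what
#' model-recovery scoring compares against). Cohort-level metadata is kept
#' under `metadata`.
#'
#' @param cohort A `catrep_cohort`.
#' @param dir Directory path (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `catrep_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "catrep_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$sessions, function(s) {
    file <- paste0(s$participant_id, ".csv")
    write_session_csv(s, file.path(dir, file))
    entry <- list(participant_id = s$participant_id, file = file,
                  condition = s$condition, structure = s$structure_kind,
                  seed = s$seed)
    if (!is.null(s$agent)) {
      entry$agent <- s$agent[c("representation", "alpha_agent",
                               "learn_burnin", "sigma_agent", "seed")]
    }
    entry
  })
  manifest <- list(metadata = cohort$metadata, sessions = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir, call. = FALSE)
  if (!file.exists(manifest_path)) {
    files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0L) {
      stop("empty cohort: no manifest.json and no session CSVs in ", dir,
           call. = FALSE)
    }
    sessions <- lapply(files, read_session_csv)
    return(new_cohort(sessions))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  sessions <- lapply(manifest$sessions, function(entry) {
    s <- read_session_csv(file.path(dir, entry$file))
    if (!is.null(entry$seed)) s$seed <- as.integer(entry$seed)
    if (!is.null(entry$agent)) s$agent <- entry$agent
    s
  })
  new_cohort(sessions, metadata = manifest$metadata)
}
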
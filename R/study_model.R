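#' Construct a validated study dataset
#'
#' Bundles long-format readings (one row per measurement) with optional
#' participant profiles and provenance metadata, after validating the
#' structural invariants of the alternating-device design. All violations
#' are collected and reported together rather than failing on the first.
#'
#' @param readings data.frame with columns `participant_id`, `session`
#'   (1 or 2), `position` (1..7), `device` (`"criterion"`/`"test"`),
#'   `variable` (`"SBP"`/`"DBP"`/`"HR"`), `value` (mm Hg or bpm).
#' @param profiles optional data.frame with columns `participant_id`,
#'   `sex`, `age`, `weight_kg`, `height_cm`, `arm_circ_mm`.
#' @param metadata free-form provenance list (source file, generator seed).
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `readings`, `profiles`, `metadata`, and `series_index`, a per
#'   participant x session x variable table with a `complete` flag
#'   (exactly the 7 positions present). Incomplete series are retained
#'   for descriptive statistics but excluded from protocol evaluation.
#'
#' @details Structural errors (bad domain values, device/position parity
#'   mismatches, duplicated positions, series participants missing from
#'   profiles) abort with a message listing every offending row. Values
#'   outside the plausibility bounds (30-300 mm Hg, 30-250 bpm) and
#'   incomplete series produce warnings, not errors.
#'
#' @export
study_dataset <- function(readings, profiles = NULL, metadata = list()) {
  required <- c("participant_id", "session", "position", "device",
                "variable", "value")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readings <- as.data.frame(readings)[required]
  readings$participant_id <- as.character(readings$participant_id)
  readings$session <- as.integer(readings$session)
  readings$position <- as.integer(readings$position)
  readings$device <- as.character(readings$device)
  readings$variable <- as.character(readings$variable)
  if (!is.numeric(readings$value)) {
    suppressWarnings(v <- as.numeric(as.character(readings$value)))
    bad <- which(is.na(v) & !is.na(readings$value))
    if (length(bad) > 0L) {
      stop("parse error: non-numeric value in row(s): ",
           paste(head(bad, 20L), collapse = ", "), call. = FALSE)
    }
    readings$value <- v
  }

  problems <- character(0)
  bad_session <- which(!readings$session %in% c(1L, 2L))
  if (length(bad_session) > 0L) {
    problems <- c(problems, paste0("session not in {1,2} in row(s): ",
                                   paste(head(bad_session, 20L), collapse = ", ")))
  }
  bad_pos <- which(!readings$position %in% 1:7)
  if (length(bad_pos) > 0L) {
    problems <- c(problems, paste0("position not in 1..7 in row(s): ",
                                   paste(head(bad_pos, 20L), collapse = ", ")))
  }
  bad_dev <- which(!readings$device %in% ESH_DEVICES)
  if (length(bad_dev) > 0L) {
    problems <- c(problems, paste0("unknown device in row(s): ",
                                   paste(head(bad_dev, 20L), collapse = ", ")))
  }
  bad_var <- which(!readings$variable %in% ESH_VARIABLES)
  if (length(bad_var) > 0L) {
    problems <- c(problems, paste0("unknown variable in row(s): ",
                                   paste(head(bad_var, 20L), collapse = ", ")))
  }
  ok_domain <- !seq_len(nrow(readings)) %in%
    c(bad_session, bad_pos, bad_dev, bad_var)
  parity_bad <- which(ok_domain &
                        readings$device != device_for_position(pmax(pmin(readings$position, 7L), 1L)))
  if (length(parity_bad) > 0L) {
    problems <- c(problems,
                  paste0("integrity error: device/position parity mismatch in row(s): ",
                         paste(head(parity_bad, 20L), collapse = ", "),
                         " (positions 1,3,5,7 must be criterion; 2,4,6 test)"))
  }
  key <- paste(readings$participant_id, readings$session,
               readings$variable, readings$position, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    problems <- c(problems, paste0("duplicated participant/session/variable/position in row(s): ",
                                   paste(head(dup, 20L), collapse = ", ")))
  }
  if (!is.null(profiles)) {
    profiles <- as.data.frame(profiles)
    if (!"participant_id" %in% names(profiles)) {
      problems <- c(problems, "profiles lack a participant_id column")
    } else {
      profiles$participant_id <- as.character(profiles$participant_id)
      orphan <- setdiff(unique(readings$participant_id), profiles$participant_id)
      if (length(orphan) > 0L) {
        problems <- c(problems, paste0("series participant(s) absent from profiles: ",
                                       paste(head(orphan, 20L), collapse = ", ")))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("study validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  lim <- VALUE_BOUNDS[readings$variable]
  lo <- vapply(lim, `[`, numeric(1), 1L)
  hi <- vapply(lim, `[`, numeric(1), 2L)
  out_of_range <- which(!is.na(readings$value) &
                          (readings$value < lo | readings$value > hi))
  if (length(out_of_range) > 0L) {
    warning(length(out_of_range),
            " reading(s) outside plausibility bounds (kept, not truncated); ",
            "first rows: ", paste(head(out_of_range, 10L), collapse = ", "),
            call. = FALSE)
  }

  idx <- series_index(readings)
  n_inc <- sum(!idx$complete)
  if (n_inc > 0L) {
    warning(n_inc, " incomplete series (fewer than 7 positions or missing ",
            "values) flagged; excluded from protocol evaluation, retained ",
            "for descriptive statistics", call. = FALSE)
  }

  structure(list(readings = readings, profiles = profiles,
                 metadata = metadata, series_index = idx),
            class = "study_dataset")
}

## one row per participant x session x variable with a completeness flag
series_index <- function(readings) {
  if (nrow(readings) == 0L) {
    return(data.frame(participant_id = character(0), session = integer(0),
                      variable = character(0), complete = logical(0)))
  }
  key <- interaction(readings$participant_id, readings$session,
                     readings$variable, drop = TRUE, sep = "\r")
  npos <- tapply(readings$position, key,
                 function(p) length(unique(p[!is.na(p)])))
  nok <- tapply(readings$value, key, function(v) sum(!is.na(v)))
  parts <- do.call(rbind, strsplit(names(npos), "\r", fixed = TRUE))
  data.frame(participant_id = parts[, 1L],
             session = as.integer(parts[, 2L]),
             variable = parts[, 3L],
             complete = as.integer(npos) == 7L & as.integer(nok) == 7L,
             stringsAsFactors = FALSE)
}

#' @export
print.study_dataset <- function(x, ...) {
  np <- length(unique(x$readings$participant_id))
  cat("ESH validation study dataset\n")
  cat("  participants:", np, "\n")
  cat("  readings:    ", nrow(x$readings), "\n")
  cat("  series:      ", nrow(x$series_index),
      sprintf("(%d complete)", sum(x$series_index$complete)), "\n")
  cat("  variables:   ", paste(sort(unique(x$readings$variable)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a study from a long-format CSV file
#'
#' The canonical interchange format is one row per reading with columns
#' `participant_id,session,position,device,variable,value`. A file using
#' different column names is adapted via `schema`, a named character
#' vector mapping canonical names to the file's column names. A wide
#' seven-column dialect is accepted by supplying `schema$position_cols`,
#' a character vector of the 7 per-position value columns in order
#' (the `device` column is then implied by position parity).
#'
#' @param path CSV file path.
#' @param schema optional named list or character vector; see Details.
#' @param profiles_path optional CSV of participant profiles
#'   (`participant_id,sex,age,weight_kg,height_cm,arm_circ_mm`).
#' @return a [study_dataset]
#' @export
read_study <- function(path, schema = NULL, profiles_path = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  schema <- as.list(schema)

  if (!is.null(schema$position_cols)) {
    pos_cols <- schema$position_cols
    if (length(pos_cols) != 7L) {
      stop("schema error: position_cols must name exactly 7 columns", call. = FALSE)
    }
    id_col <- schema$participant_id %||% "participant_id"
    se_col <- schema$session %||% "session"
    va_col <- schema$variable %||% "variable"
    for (cc in c(id_col, se_col, va_col, pos_cols)) {
      if (!cc %in% names(raw)) {
        stop("schema error: missing column: ", cc, call. = FALSE)
      }
    }
    long <- do.call(rbind, lapply(seq_len(7L), function(p) {
      data.frame(participant_id = raw[[id_col]],
                 session = raw[[se_col]],
                 position = p,
                 device = device_for_position(p),
                 variable = raw[[va_col]],
                 value = raw[[pos_cols[p]]],
                 stringsAsFactors = FALSE)
    }))
    raw <- long
  } else if (length(schema) > 0L) {
    map <- unlist(schema)
    for (canon in names(map)) {
      if (!map[[canon]] %in% names(raw)) {
        stop("schema error: missing column: ", map[[canon]], call. = FALSE)
      }
      names(raw)[names(raw) == map[[canon]]] <- canon
    }
  }

  profiles <- NULL
  if (!is.null(profiles_path)) {
    if (!file.exists(profiles_path)) {
      stop("profiles file not found: ", profiles_path, call. = FALSE)
    }
    profiles <- read.csv(profiles_path, stringsAsFactors = FALSE)
  }
  study_dataset(raw, profiles = profiles,
                metadata = list(source = path))
}

#' Write a study dataset to CSV
#'
#' Writes the canonical long format; `read_study(write_study(d))`
#' reproduces the readings exactly.
#'
#' @param dataset a [study_dataset]
#' @param path output CSV path for the readings
#' @param profiles_path optional output CSV path for participant profiles
#' @return `path`, invisibly
#' @export
write_study <- function(dataset, path, profiles_path = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  write.csv(dataset$readings, path, row.names = FALSE, quote = FALSE)
  if (!is.null(profiles_path) && !is.null(dataset$profiles)) {
    write.csv(dataset$profiles, profiles_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Participant eligibility flags
#'
#' Computes the protocol's demographic eligibility from a profiles table:
#' age at least 25 years and arm circumference within 220-320 mm.
#' Ineligible participants are flagged, never silently dropped.
#'
#' @param profiles data.frame with `age` and `arm_circ_mm` columns
#' @return the profiles data.frame with a logical `eligible` column and
#'   a derived `bmi` column when weight/height are present
#' @export
eligibility_flags <- function(profiles) {
  profiles <- as.data.frame(profiles)
  stopifnot(all(c("age", "arm_circ_mm") %in% names(profiles)))
  profiles$eligible <- profiles$age >= 25 &
    profiles$arm_circ_mm >= 220 & profiles$arm_circ_mm <= 320
  if (all(c("weight_kg", "height_cm") %in% names(profiles))) {
    profiles$bmi <- profiles$weight_kg / (profiles$height_cm / 100)^2
  }
  profiles
}

## matrix of complete 7-vectors for one session x variable: one row per
## participant, columns positions 1..7, rownames participant ids
series_matrix <- function(dataset, session, variable, participants = NULL) {
  r <- dataset$readings
  r <- r[r$session == session & r$variable == variable, , drop = FALSE]
  idx <- dataset$series_index
  keep <- idx$participant_id[idx$session == session &
                               idx$variable == variable & idx$complete]
  if (!is.null(participants)) keep <- intersect(keep, participants)
  keep <- sort(keep)
  r <- r[r$participant_id %in% keep, , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(keep), ncol = 7L,
              dimnames = list(keep, paste0("p", 1:7)))
  m[cbind(match(r$participant_id, keep), r$position)] <- r$value
  m
}

#' Participants with complete series for every requested session and variable
#'
#' @param dataset a [study_dataset]
#' @param variables character vector of variables
#' @param sessions integer vector of sessions
#' @return sorted character vector of participant ids
#' @export
complete_participants <- function(dataset, variables = ESH_VARIABLES,
                                  sessions = c(1L, 2L)) {
  idx <- dataset$series_index
  ids <- unique(idx$participant_id)
  needed <- expand.grid(session = sessions, variable = variables,
                        stringsAsFactors = FALSE)
  ok <- vapply(ids, function(id) {
    sub <- idx[idx$participant_id == id & idx$complete, , drop = FALSE]
    all(mapply(function(s, v) any(sub$session == s & sub$variable == v),
               needed$session, needed$variable))
  }, logical(1))
  sort(ids[ok])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
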
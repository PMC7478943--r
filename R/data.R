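required_cols <- c("ID", "CYCLE", "TIME", "DOSE", "DV",
                   "AGE", "SEX", "ENTITY", "MONO", "ADH")
sex_levels <- c("male", "female")
entity_levels <- c("colorectal", "breast", "other")
adh_levels <- c(">100%", "90-100%", "<90%")

#' Read a longitudinal toxicity dataset
#'
#' Reads and validates the standard long-format CSV: one row per
#' patient-cycle with columns `ID`, `CYCLE` (integer >= 0), `TIME` (cycles),
#' `DOSE` (daily dose in mg during the cycle ending at `TIME`), `DV`
#' (observed grade 0--3, blank on dosing-only rows), `AGE`, `SEX`
#' (`male`/`female`), `ENTITY` (`colorectal`/`breast`/`other`), `MONO`
#' (0/1 or logical), `ADH` (`>100%`/`90-100%`/`<90%`). Every subject needs a
#' baseline row (`CYCLE` 0, `TIME` 0, `DV` 0: patients are asymptomatic
#' before treatment) and strictly increasing times.
#'
#' @param path CSV file path.
#' @return validated `data.frame`.
#' @export
read_dataset <- function(path) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(data)
}

#' @param data a dataset `data.frame` in the format of [read_dataset()].
#' @rdname read_dataset
#' @export
validate_dataset <- function(data) {
  miss <- setdiff(required_cols, names(data))
  if (length(miss)) stop("parse error: missing column(s): ",
                         paste(miss, collapse = ", "))
  rown <- seq_len(nrow(data))
  bad <- which(!(is.na(data$DV) | data$DV %in% 0:3))
  if (length(bad)) {
    stop("parse error: DV must be a grade 0-3 or blank; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.na(data$DOSE) & (data$DOSE < 0 | !is.finite(data$DOSE)))
  if (length(bad)) {
    stop("parse error: DOSE must be >= 0; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  chk_level <- function(col, levels) {
    bad <- which(!data[[col]] %in% levels)
    if (length(bad)) {
      stop("parse error: ", col, " must be one of ",
           paste(levels, collapse = "/"), "; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  chk_level("SEX", sex_levels)
  chk_level("ENTITY", entity_levels)
  chk_level("ADH", adh_levels)
  for (id in unique(data$ID)) {
    idx <- which(data$ID == id)
    sub <- data[idx, ]
    base <- which(sub$CYCLE == 0)
    if (length(base) != 1) {
      stop("parse error: subject ", id,
           " must have exactly one baseline row (CYCLE 0); rows ",
           paste(utils::head(idx, 5), collapse = ", "))
    }
    if (!isTRUE(sub$DV[base] == 0) || sub$TIME[base] != 0) {
      stop("parse error: subject ", id,
           " baseline row must have TIME 0 and DV 0 (row ", idx[base], ")")
    }
    o <- order(sub$TIME)
    if (any(diff(sub$TIME[o]) <= 0)) {
      stop("parse error: subject ", id, " has non-increasing TIME values")
    }
  }
  data[order(data$ID, data$TIME), , drop = FALSE]
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Split a validated dataset into per-subject records:
# list(id, age, sex, entity, mono, adherence,
#      cycles = data.frame(cycle, time, dose, grade)).
records_from_data <- function(data) {
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    sub <- data[data$ID == id, , drop = FALSE]
    sub <- sub[order(sub$TIME), , drop = FALSE]
    post <- sub[sub$CYCLE > 0, , drop = FALSE]
    list(id = id,
         age = sub$AGE[1],
         sex = sub$SEX[1],
         entity = sub$ENTITY[1],
         mono = as.logical(sub$MONO[1]),
         adherence = sub$ADH[1],
         cycles = data.frame(cycle = post$CYCLE, time = post$TIME,
                             dose = post$DOSE, grade = post$DV))
  })
}

# Per-subject segment structure consumed by the C++ likelihood: segment
# lengths from baseline (time 0), scaled design matrices for the intercept
# and MET targets, and the observed grade (-1 when unobserved).
build_subject <- function(record, spec, dose_center) {
  seg <- record$cycles
  dt <- diff(c(0, seg$time))
  obs <- ifelse(is.na(seg$grade), -1L, as.integer(seg$grade))
  list(dt = as.numeric(dt),
       Xint = design_matrix(spec$intercept, record, seg, dose_center),
       Xmet = design_matrix(spec$met, record, seg, dose_center),
       obs = obs)
}

build_subjects <- function(records, spec, dose_center) {
  lapply(records, build_subject, spec = spec, dose_center = dose_center)
}

# Drop subjects with no post-baseline observation: baseline is
# deterministically grade 0 and contributes nothing to the likelihood.
drop_empty_records <- function(records, quiet = FALSE) {
  has_obs <- vapply(records, function(r) any(!is.na(r$cycles$grade)), TRUE)
  if (any(!has_obs) && !quiet) {
    message("dropping ", sum(!has_obs),
            " subject(s) with no post-baseline observations")
  }
  records[has_obs]
}

#' Observed transition counts between adverse-event grades
#'
#' Counts transitions between consecutive observed grades (including the
#' deterministic grade-0 baseline as the first observation of every subject),
#' in the layout of a 4x4 from-to table.
#'
#' @param data a validated dataset `data.frame`.
#' @return 4x4 integer matrix, rows = from grade, columns = to grade.
#' @export
transition_counts <- function(data) {
  recs <- records_from_data(validate_dataset(data))
  tab <- matrix(0L, 4, 4, dimnames = list(from = paste0("grade", 0:3),
                                          to = paste0("grade", 0:3)))
  for (r in recs) {
    g <- c(0, r$cycles$grade[!is.na(r$cycles$grade)])
    if (length(g) < 2) next
    for (k in seq_len(length(g) - 1)) {
      tab[g[k] + 1, g[k + 1] + 1] <- tab[g[k] + 1, g[k + 1] + 1] + 1L
    }
  }
  tab
}
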
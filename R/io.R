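#' Write and read a finite population
#'
#' The population file holds one integer bag count per line.  A small
#' key=value sidecar (`<file>.meta`) records the generating parameters when
#' they are known (`N`, `p`, `lambda`, `seed`), so a population can be
#' traced back to its model.
#'
#' @param pop a [finite_population()].
#' @param file path of the population file.
#' @return `write_population()` returns `file` invisibly;
#'   `read_population()` returns a [finite_population()] with any sidecar
#'   metadata attached as attribute `"meta"`.
#' @export
write_population <- function(pop, file) {
  stopifnot(inherits(pop, "finite_population"))
  writeLines(as.character(pop$y), file)
  meta <- attr(pop, "meta")
  fields <- c(list(N = pop$N), if (!is.null(meta)) meta)
  writeLines(paste0(names(fields), "=",
                    vapply(fields, function(v) format(v, digits = 17),
                           character(1))),
             paste0(file, ".meta"))
  invisible(file)
}

#' @rdname write_population
#' @export
read_population <- function(file) {
  y <- scan(file, what = integer(), quiet = TRUE)
  if (length(y) == 0L) stop("population file '", file, "' is empty")
  pop <- finite_population(y)
  metafile <- paste0(file, ".meta")
  if (file.exists(metafile)) {
    lines <- readLines(metafile)
    kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
    meta <- lapply(kv, function(x) {
      v <- suppressWarnings(as.numeric(x[2]))
      if (is.na(v) && x[2] != "NA") x[2] else v
    })
    names(meta) <- vapply(kv, `[[`, character(1), 1)
    if (!is.null(meta$N) && meta$N != pop$N)
      stop("sidecar says N = ", meta$N, " but file holds ", pop$N, " bags")
    attr(pop, "meta") <- meta
  }
  pop
}

#' Write and read multiphase survey data
#'
#' Serializes a survey realization as two tab-separated tables plus a
#' key=value metadata file, the exact format consumed by the estimation
#' side: `<prefix>_respondents.tsv` with columns `(phase, unit_id, bag)`
#' (one row per responding hunter; `unit_id` may be `NA` when unit identity
#' was not tracked), `<prefix>_phases.tsv` with columns
#' `(phase, n_s, n_r, n_m)`, and `<prefix>_meta.txt` with at least `N`.
#'
#' @param survey a `"survey_realization"` from [run_survey()], or a plain
#'   list of [phase_data()] (then give `N`).
#' @param prefix path prefix for the three files.
#' @param N population size (taken from `survey` when available).
#' @return `write_survey()` returns the three file paths invisibly;
#'   `read_survey()` returns a list with `phases` (list of [phase_data()])
#'   and `N`.
#' @export
write_survey <- function(survey, prefix, N = NULL) {
  if (inherits(survey, "survey_realization")) {
    N <- survey$N
    sets <- survey$sets
    phases <- survey$phases
  } else {
    phases <- survey
    sets <- NULL
    if (is.null(N)) stop("'N' is required when 'survey' is a phase list")
  }
  resp <- do.call(rbind, lapply(seq_along(phases), function(i) {
    ph <- phases[[i]]
    if (ph$n_r == 0L) return(NULL)
    data.frame(phase = ph$i,
               unit_id = if (!is.null(sets)) sets[[i]]$r else NA_integer_,
               bag = ph$y_r)
  }))
  if (is.null(resp))
    resp <- data.frame(phase = integer(0), unit_id = integer(0),
                       bag = numeric(0))
  summ <- data.frame(phase = vapply(phases, `[[`, integer(1), "i"),
                     n_s = vapply(phases, `[[`, integer(1), "n_s"),
                     n_r = vapply(phases, `[[`, integer(1), "n_r"),
                     n_m = vapply(phases, `[[`, integer(1), "n_m"))
  files <- paste0(prefix, c("_respondents.tsv", "_phases.tsv", "_meta.txt"))
  write.table(resp, files[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summ, files[2], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0("N=", N), files[3])
  invisible(files)
}

#' @rdname write_survey
#' @export
read_survey <- function(prefix) {
  files <- paste0(prefix, c("_respondents.tsv", "_phases.tsv", "_meta.txt"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing survey file(s): ", paste(missing, collapse = ", "))
  resp <- read.delim(files[1])
  summ <- read.delim(files[2])
  need <- c("phase", "n_s", "n_r", "n_m")
  if (!all(need %in% names(summ)))
    stop("phase table must have columns ", paste(need, collapse = ", "))
  if (!all(c("phase", "bag") %in% names(resp)))
    stop("respondent table must have columns phase, bag")
  meta <- readLines(files[3])
  Nline <- grep("^N=", meta, value = TRUE)
  if (!length(Nline)) stop("metadata file lacks an 'N=' entry")
  N <- as.integer(sub("^N=", "", Nline[1]))
  summ <- summ[order(summ$phase), ]
  if (!identical(as.integer(summ$phase), seq_len(nrow(summ))))
    stop("phases must be numbered consecutively from 1")
  phases <- lapply(seq_len(nrow(summ)), function(i) {
    phase_data(i, summ$n_s[i], summ$n_r[i], summ$n_m[i],
               resp$bag[resp$phase == i])
  })
  list(phases = phases, N = N)
}

#' Write an estimate result as a flat key=value record
#'
#' @param est an `"estimate_result"`.
#' @param file output path ("" prints to the console).
#' @return The path, invisibly.
#' @export
write_estimate <- function(est, file = "") {
  stopifnot(inherits(est, "estimate_result"))
  w <- est$phase_weights
  lines <- c(
    paste0("estimator=", est$estimator),
    paste0("N=", est$N),
    paste0("mean_hat=", format(est$mean_hat, digits = 17)),
    paste0("total_hat=", format(est$total_hat, digits = 17)),
    paste0("var_hat_total=", format(est$var_hat_total, digits = 17)),
    paste0("var_hat_mean=", format(est$var_hat_mean, digits = 17)),
    paste0("se_total=", format(est$se_total, digits = 17)),
    if (length(w)) {
      wn <- names(w)
      if (is.null(wn)) wn <- rep("", length(w))
      paste0(ifelse(wn == "W_final", "W_final", paste0("W_R", seq_along(w))),
             "=", format(unname(w), digits = 17))
    })
  writeLines(lines, file)
  invisible(file)
}
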
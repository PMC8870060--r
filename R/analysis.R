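#' Read a fitting-session score table
#'
#' One row per listener: initial word recognition score (20-word test, out
#' of ten), the fixed per-listener SNR, the scores of the 13 candidate maps
#' (P1-P4, C1-C9; trailing cells empty if the listener abandoned the
#' procedure), the label of the selected map, and the final score (20-word
#' test, 45-60 days after fitting). The packaged table \code{table2.csv}
#' transcribes the 27-listener clinical session set shipped with the
#' package.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame of class \code{session_table}.
#' @export
read_session_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table2.csv", package = "eafit",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "initial_wrs", "snr_db", candidate_labels(),
            "selected", "final_wrs")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("session table lacks columns: ", paste(missing_cols, collapse = ", "))
  class(tab) <- c("session_table", "data.frame")
  tab
}

candidate_labels <- function() c(paste0("P", 1:4), paste0("C", 1:9))

#' Check session-table invariants
#'
#' Verifies, per row, that missing candidate scores occur only in trailing
#' positions (the abandon pattern) and that the selected map's score equals
#' the row maximum over non-missing candidate scores.
#'
#' @param tab a \code{session_table}.
#' @return data.frame of violations (\code{patient}, \code{rule},
#'   \code{detail}); zero rows if the table is consistent.
#' @export
validate_session_table <- function(tab) {
  labs <- candidate_labels()
  out <- list()
  bad <- function(patient, rule, detail)
    out[[length(out) + 1L]] <<- data.frame(patient = patient, rule = rule,
                                           detail = detail)
  for (i in seq_len(nrow(tab))) {
    s <- as.numeric(tab[i, labs])
    miss <- is.na(s)
    if (any(miss) && any(diff(miss) < 0))
      bad(tab$patient[i], "trailing_missing",
          "missing candidate scores are not a trailing block")
    if (all(miss)) { bad(tab$patient[i], "no_scores", "no candidate scores"); next }
    sel <- tab$selected[i]
    if (!sel %in% labs) { bad(tab$patient[i], "selected_label",
                              paste("unknown label", sel)); next }
    if (is.na(s[match(sel, labs)]))
      bad(tab$patient[i], "selected_missing",
          paste("selected map", sel, "has no score"))
    else if (s[match(sel, labs)] < max(s, na.rm = TRUE))
      bad(tab$patient[i], "selected_not_max",
          sprintf("selected %s scores %g < row maximum %g",
                  sel, s[match(sel, labs)], max(s, na.rm = TRUE)))
  }
  if (length(out) == 0L)
    data.frame(patient = integer(0), rule = character(0),
               detail = character(0))
  else do.call(rbind, out)
}

#' Summary statistics of initial and final word recognition scores
#'
#' Scores are out of ten; percentages are the same values times ten.
#' The spread is reported both as the sample standard deviation (n - 1
#' denominator) and as the standard error of the mean.
#'
#' @param tab a \code{session_table} with complete \code{initial_wrs} and
#'   \code{final_wrs} columns.
#' @return list with components \code{initial} and \code{final}, each a
#'   list with \code{n}, \code{mean}, \code{sd}, \code{sem}, \code{median},
#'   \code{min}, \code{max}, \code{mean_percent}, \code{sd_percent}.
#' @export
summarize_wrs <- function(tab) {
  one <- function(x, label) {
    x <- as.numeric(x)
    if (length(x) == 0L || all(is.na(x)))
      stop("empty ", label, " score column")
    if (anyNA(x)) stop("missing values in ", label, " score column")
    list(n = length(x), mean = mean(x), sd = stats::sd(x),
         sem = stats::sd(x) / sqrt(length(x)),
         median = stats::median(x), min = min(x), max = max(x),
         mean_percent = wrs_to_percent(mean(x)),
         sd_percent = 10 * stats::sd(x))
  }
  list(initial = one(tab$initial_wrs, "initial"),
       final = one(tab$final_wrs, "final"))
}

#' Which generation produced each listener's selected map
#'
#' Classifies the selected label: P1-P4 are the randomly initialized
#' parents, C1-C3 the first, C4-C6 the second, C7-C9 the third generation
#' of children.
#'
#' @param tab a \code{session_table}.
#' @return named integer vector with entries \code{parents}, \code{gen1},
#'   \code{gen2}, \code{gen3}.
#' @export
best_generation_counts <- function(tab) {
  cls <- vapply(tab$selected, function(lab) {
    if (grepl("^P[1-4]$", lab)) return("parents")
    if (grepl("^C[1-3]$", lab)) return("gen1")
    if (grepl("^C[4-6]$", lab)) return("gen2")
    if (grepl("^C[7-9]$", lab)) return("gen3")
    stop("unknown selected-map label: ", lab)
  }, character(1))
  out <- c(parents = 0L, gen1 = 0L, gen2 = 0L, gen3 = 0L)
  t <- table(cls)
  out[names(t)] <- as.integer(t)
  out
}

#' Listeners whose top score was shared by several maps
#'
#' Counts rows in which at least two non-missing candidate scores equal the
#' row maximum (the listener then chose among the tied maps by sound
#' quality).
#'
#' @param tab a \code{session_table}.
#' @return list with \code{count} and \code{patients} (their ids).
#' @export
tie_counts <- function(tab) {
  labs <- candidate_labels()
  tied <- vapply(seq_len(nrow(tab)), function(i) {
    s <- as.numeric(tab[i, labs])
    s <- s[!is.na(s)]
    if (length(s) == 0L) stop("row ", i, " has no candidate scores")
    sum(s == max(s)) >= 2L
  }, logical(1))
  list(count = sum(tied), patients = tab$patient[tied])
}

#' Convert a score out of ten to percent
#'
#' @param score_out_of_ten numeric score(s) in \code{[0, 10]}.
#' @return the score(s) times ten.
#' @export
wrs_to_percent <- function(score_out_of_ten) {
  if (any(score_out_of_ten < 0 | score_out_of_ten > 10, na.rm = TRUE))
    stop("scores out of ten must lie in [0, 10]")
  10 * score_out_of_ten
}

#' Full report over a session table
#'
#' Bundles [summarize_wrs()], [best_generation_counts()], [tie_counts()]
#' and the paired signed-rank comparison of final versus initial scores.
#'
#' @param tab a \code{session_table}; the packaged table by default.
#' @return list with components \code{summary}, \code{best_generation},
#'   \code{ties}, \code{wilcoxon} (final vs initial), \code{n_patients}.
#' @export
session_table_report <- function(tab = read_session_table()) {
  list(
    n_patients = nrow(tab),
    summary = summarize_wrs(tab),
    best_generation = as.list(best_generation_counts(tab)),
    ties = tie_counts(tab),
    wilcoxon = wilcoxon_signed_rank(tab$final_wrs, tab$initial_wrs)
  )
}
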
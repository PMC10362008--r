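#' Measure schema for a neurocognitive battery
#'
#' A measure schema is an ordered table describing each score in a battery:
#' its identifier, the instrument it comes from, the neurocognitive
#' subfunction it taps, the score label, whether higher raw scores reflect
#' better performance, and whether the score must be reverse scored before
#' modelling so that higher always means better.
#'
#' @param measures A data frame with columns `measure_id`, `battery`,
#'   `subfunction`, `score_label`, `higher_is_better_raw`, `reverse_score`.
#' @return An object of class `measure_schema` (a validated data frame).
#' @seealso [default_schema()] for the bundled 27-measure battery.
#' @export
measure_schema <- function(measures) {
  required <- c("measure_id", "battery", "subfunction", "score_label",
                "higher_is_better_raw", "reverse_score")
  if (!is.data.frame(measures)) {
    stop("`measures` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(measures))
  if (length(missing_cols) > 0) {
    stop("schema is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  measures$measure_id <- as.character(measures$measure_id)
  if (anyDuplicated(measures$measure_id)) {
    dup <- unique(measures$measure_id[duplicated(measures$measure_id)])
    stop("duplicate measure_id in schema: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  allowed <- c("DKEFS", "ANT", "CNB", "DigitSpan", "RAVLT")
  bad <- setdiff(unique(measures$battery), allowed)
  if (length(bad) > 0) {
    stop("unknown battery label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  measures$higher_is_better_raw <- as.logical(measures$higher_is_better_raw)
  measures$reverse_score <- as.logical(measures$reverse_score)
  rownames(measures) <- NULL
  structure(measures[, required], class = c("measure_schema", "data.frame"))
}

#' The bundled 27-measure battery schema
#'
#' The default schema covers the 27 scores of a multi-instrument
#' neurocognitive battery: nine Delis-Kaplan Executive Function System
#' (D-KEFS) tests contributing twelve scores, the three Attention Network
#' Test (ANT) efficiency scores, eight Penn Computerized Neurocognitive
#' Battery (CNB) tests, Digit Span forwards and backwards, and the Rey
#' Auditory Verbal Learning Test delayed recall. The three ANT efficiency
#' scores are time based (lower raw values are better) and are the only
#' measures flagged for reverse scoring.
#'
#' @return A [measure_schema] with 27 rows.
#' @examples
#' nrow(default_schema())
#' @export
default_schema <- function() {
  m <- function(id, battery, subfn, label, higher = TRUE, reverse = FALSE) {
    data.frame(measure_id = id, battery = battery, subfunction = subfn,
               score_label = label, higher_is_better_raw = higher,
               reverse_score = reverse, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    m("dkefs_twenty_questions", "DKEFS",
      "abstract categorization, visual attention, and perception",
      "Total Questions Asked"),
    m("dkefs_design_fluency", "DKEFS",
      "cognitive flexibility and inhibition (visual/motor)",
      "Total Correct"),
    m("dkefs_proverb", "DKEFS", "verbal abstraction", "Total Achievement"),
    m("dkefs_tower_achievement", "DKEFS",
      "spatial planning and rule learning", "Total Achievement"),
    m("dkefs_tower_rule_violations", "DKEFS",
      "spatial planning and error detection in planning",
      "Rule Violations Per Item Ratio"),
    m("dkefs_trails_number_sequencing", "DKEFS", "attention",
      "Number Sequencing"),
    m("dkefs_trails_number_letter_switching", "DKEFS",
      "cognitive flexibility (visual)", "Number-Letter Switching"),
    m("dkefs_verbal_fluency_category_switching", "DKEFS",
      "cognitive flexibility (verbal)", "Category Switching"),
    m("dkefs_cwi_inhibition_color_naming", "DKEFS",
      "inhibition adjusted for basic naming skills",
      "Inhibition-Color Naming"),
    m("dkefs_cwi_inhibition_switching_color_naming", "DKEFS",
      "cognitive flexibility adjusted for basic naming skills",
      "Inhibition/Switching-Color Naming"),
    m("dkefs_cwi_inhibition_errors", "DKEFS",
      "error detection related to inhibition",
      "Inhibition uncorrected error"),
    m("dkefs_cwi_inhibition_switching_errors", "DKEFS",
      "error detection related to cognitive control",
      "Inhibition/Switching uncorrected error"),
    m("ant_alerting", "ANT", "alerting attention",
      "Time-based alerting efficiency score", higher = FALSE,
      reverse = TRUE),
    m("ant_orienting", "ANT", "orienting attention",
      "Time-based orienting efficiency score", higher = FALSE,
      reverse = TRUE),
    m("ant_executive", "ANT", "executive attention and inhibition",
      "Time-based executive attention efficiency score", higher = FALSE,
      reverse = TRUE),
    m("cnb_mouse_practice", "CNB", "sensorimotor processing speed",
      "Efficiency score"),
    m("cnb_continuous_performance", "CNB", "sustained attention",
      "Efficiency score"),
    m("cnb_conditional_exclusion", "CNB",
      "abstraction and cognitive flexibility", "Efficiency score"),
    m("cnb_emotion_differentiation", "CNB", "social cognition",
      "Efficiency score"),
    m("cnb_emotion_identification", "CNB", "social cognition",
      "Efficiency score"),
    m("cnb_word_memory", "CNB", "episodic memory (verbal)",
      "Efficiency score"),
    m("cnb_visual_object_learning", "CNB", "episodic memory (spatial)",
      "Efficiency score"),
    m("cnb_verbal_reasoning", "CNB", "language reasoning",
      "Efficiency score"),
    m("cnb_finger_tapping", "CNB", "sensorimotor processing speed",
      "Sum score for mean dominant and non-dominant hand taps"),
    m("digit_span_forward", "DigitSpan", "attention and working memory",
      "Raw score for longest length forward"),
    m("digit_span_backward", "DigitSpan", "working memory",
      "Raw score for longest length backwards"),
    m("ravlt_delayed_recall", "RAVLT", "learning and memory",
      "Total correct scores")
  )
  measure_schema(rows)
}

#' @export
print.measure_schema <- function(x, ...) {
  cat("<measure_schema> with", nrow(x), "measures\n")
  cat("  batteries:", paste(sprintf("%s (%d)", names(table(x$battery)),
                                    table(x$battery)), collapse = ", "), "\n")
  cat("  reverse scored:",
      paste(x$measure_id[x$reverse_score], collapse = ", "), "\n")
  invisible(x)
}
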
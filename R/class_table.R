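#' Class tables for scene rendering and graph extraction
#'
#' A class table enumerates the semantic classes a scene can contain:
#' exactly one background class plus anatomy, tool and miscellaneous classes,
#' each with a reference render colour. Class ids are contiguous from 0.
#' The default table is a reduced analogue of a cataract-surgery label set
#' (setting-II style grouping into anatomy / tool / miscellaneous): 1
#' background, 3 anatomy, 4 tool and 2 miscellaneous classes.
#'
#' @param entries data.frame with columns `class_id`, `name`, `category`
#'   (one of `"background"`, `"anatomy"`, `"tool"`, `"misc"`) and `r`, `g`,
#'   `b` reference colours in `[0, 1]`.
#' @return a validated `class_table` data.frame.
#' @export
#' @examples
#' ct <- default_class_table()
#' subset(ct, category == "tool")
class_table <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("class_id", "name", "category", "r", "g", "b")
  if (!all(need %in% names(entries))) {
    stop("class table needs columns: ", paste(need, collapse = ", "))
  }
  entries <- entries[order(entries$class_id), , drop = FALSE]
  ids <- entries$class_id
  if (anyDuplicated(ids) || !identical(as.integer(ids), seq_along(ids) - 1L)) {
    stop("class_ids must be unique and contiguous from 0")
  }
  if (!all(entries$category %in% c("background", "anatomy", "tool", "misc"))) {
    stop("unknown category")
  }
  if (sum(entries$category == "background") != 1L) {
    stop("exactly one background class required")
  }
  if (!any(entries$category == "anatomy") || !any(entries$category == "tool")) {
    stop("need at least one anatomy and one tool class")
  }
  rownames(entries) <- NULL
  class(entries) <- c("class_table", "data.frame")
  entries
}

#' @rdname class_table
#' @export
default_class_table <- function() {
  class_table(data.frame(
    class_id = 0:9,
    name = c(
      "background", "sclera", "iris", "pupil",
      "forceps", "cannula", "phaco_handpiece", "spatula",
      "tape", "retractor"
    ),
    category = c(
      "background", "anatomy", "anatomy", "anatomy",
      "tool", "tool", "tool", "tool",
      "misc", "misc"
    ),
    r = c(0.02, 0.90, 0.42, 0.20, 0.78, 0.18, 0.92, 0.12, 0.55, 0.85),
    g = c(0.02, 0.72, 0.58, 0.18, 0.80, 0.70, 0.85, 0.78, 0.58, 0.25),
    b = c(0.03, 0.68, 0.80, 0.28, 0.84, 0.32, 0.20, 0.85, 0.95, 0.72),
    stringsAsFactors = FALSE
  ))
}

class_ids_of <- function(ct, category) ct$class_id[ct$category == category]

class_colors <- function(ct) {
  m <- as.matrix(ct[, c("r", "g", "b")])
  rownames(m) <- ct$class_id
  m
}
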
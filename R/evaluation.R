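#' True-positive rate
#'
#' TPR = TP / (TP + FN), reported at two decimals rounded half away from
#' zero (so 22 correct of 26 assigned prints as 0.85). Undefined when no
#' predictions exist; see [evaluate_predictions()], which reports such
#' rows as NA (printed as a dash).
#'
#' @param tp number of correct predictions.
#' @param fn number of incorrect predictions.
#' @return TPR rounded to 2 decimals.
#' @export
tpr <- function(tp, fn) {
  if (tp + fn < 1) stop("tpr undefined for tp + fn = 0")
  round_half_up(tp / (tp + fn), 2)
}

#' Load the shipped disease-class to efficacy-class map
#'
#' Maps each of the 18 disease classes (D1..D18) to one or two of the nine
#' efficacy classes (E1..E9) of the prior plant-efficacy gold standard.
#'
#' @param path TSV path; defaults to the shipped fixture.
#' @return named list: class id (integer as character) -> character vector
#'   of efficacy ids.
#' @export
load_efficacy_map <- function(path = jamunet_extdata("table5_efficacy_map.tsv")) {
  tab <- utils::read.delim(path, colClasses = "character")
  emap <- lapply(strsplit(tab$efficacy_ids, ","), trimws)
  names(emap) <- tab$class_id
  emap
}

#' Load a plant-efficacy gold standard from TSV
#'
#' Expected columns: `plant_id` and `efficacy_ids` (comma-separated E
#' ids). The gold standard may be partial; plants absent from it are
#' scored as misses.
#'
#' @param path TSV path.
#' @return named list: plant id -> character vector of efficacy ids.
#' @export
load_gold_standard <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  gold <- lapply(strsplit(tab$efficacy_ids, ","), trimws)
  names(gold) <- tab$plant_id
  gold
}

#' Load the shipped printed plant-disease prediction fixture
#'
#' The published list of plants assigned to each disease class by the 0.7%
#' network, with the printed Hit/Miss status and the flag marking rows
#' that disappear when the matching-score cutoff is tightened to 0.7.
#'
#' @param path TSV path; defaults to the shipped fixture.
#' @return data.frame `class_id`, `plant`, `status`, `dropped_at_0p7_score`.
#' @export
load_printed_predictions <- function(path = jamunet_extdata("table4_predictions_0p7.tsv")) {
  tab <- utils::read.delim(path, colClasses = c("integer", "character",
                                                "character", "integer"))
  names(tab) <- c("class_id", "plant", "status", "dropped_at_0p7_score")
  tab
}

#' Reconstruct a gold standard from a printed Hit/Miss prediction list
#'
#' For testing without the original (non-redistributable) gold standard: a
#' plant is credited with the efficacy classes of every disease class it
#' is printed as a Hit for. This is a synthetic test fixture consistent
#' with the published Hit rows, not a re-derivation of the underlying
#' efficacy study; Miss rows of classes whose efficacies overlap a Hit
#' class are not guaranteed to be reproduced.
#'
#' @param printed data.frame as from [load_printed_predictions()].
#' @param emap efficacy map as from [load_efficacy_map()].
#' @return named list: plant id -> character vector of efficacy ids.
#' @export
reconstruct_gold_standard <- function(printed = load_printed_predictions(),
                                      emap = load_efficacy_map()) {
  hits <- printed[printed$status == "Hit", ]
  gold <- lapply(split(hits$class_id, hits$plant), function(cls)
    sort(unique(unlist(emap[as.character(cls)]))))
  gold
}

#' Score predicted relations against an efficacy gold standard
#'
#' Each predicted (plant, disease-class) pair is checked through the
#' class-to-efficacy map: for every efficacy e mapped to class c, a plant
#' predicted for c counts as a true positive under e iff e is among the
#' plant's gold-standard efficacies (plants absent from the gold standard
#' are misses). Per (class, efficacy) row: n_assigned, TP, FN and TPR;
#' rows with no assigned plants report TPR = NA. The TPR of a class mapped
#' to several efficacies is the maximum over them.
#'
#' @param relations data.frame with `plant_id`, `class_id`.
#' @param gold named list: plant -> efficacy ids.
#' @param emap named list: class id -> efficacy ids.
#' @return list with `by_efficacy` (data.frame `class_id`, `efficacy_id`,
#'   `n_assigned`, `tp`, `fn`, `tpr`), `by_class` (data.frame `class_id`,
#'   `n_assigned`, `tpr`) and `total_assigned_plants` (distinct plants).
#' @export
evaluate_predictions <- function(relations, gold, emap) {
  bad <- setdiff(as.character(relations$class_id), names(emap))
  if (length(bad)) stop("predicted class(es) missing from efficacy map: ",
                        paste(bad, collapse = ", "))
  classes <- sort(as.integer(names(emap)))
  rows <- list()
  for (cl in classes) {
    plants <- unique(relations$plant_id[relations$class_id == cl])
    for (e in emap[[as.character(cl)]]) {
      tp_n <- sum(vapply(plants, function(p) e %in% gold[[p]], logical(1)))
      n <- length(plants)
      rows[[length(rows) + 1]] <- data.frame(
        class_id = cl, efficacy_id = e, n_assigned = n,
        tp = tp_n, fn = n - tp_n,
        tpr = if (n == 0) NA_real_ else tpr(tp_n, n - tp_n))
    }
  }
  by_eff <- do.call(rbind, rows)
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    sub <- by_eff[by_eff$class_id == cl, ]
    data.frame(class_id = cl, n_assigned = max(sub$n_assigned),
               tpr = if (all(is.na(sub$tpr))) NA_real_ else
                 max(sub$tpr, na.rm = TRUE))
  }))
  list(by_efficacy = by_eff, by_class = by_class,
       total_assigned_plants = length(unique(relations$plant_id)))
}

#' Per-prediction Hit/Miss listing
#'
#' A prediction (plant, class) is a Hit iff the plant's gold-standard
#' efficacy set intersects the efficacies mapped to the class; otherwise
#' (including plants absent from the gold standard) it is a Miss.
#'
#' @param relations data.frame with `plant_id`, `class_id`.
#' @param gold named list: plant -> efficacy ids.
#' @param emap named list: class id -> efficacy ids.
#' @return data.frame `class_id`, `plant_id`, `status`.
#' @export
hit_miss_table <- function(relations, gold, emap) {
  status <- vapply(seq_len(nrow(relations)), function(k) {
    p <- relations$plant_id[k]
    eff <- emap[[as.character(relations$class_id[k])]]
    if (length(intersect(gold[[p]], eff))) "Hit" else "Miss"
  }, character(1))
  data.frame(class_id = relations$class_id, plant_id = relations$plant_id,
             status = status)
}
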
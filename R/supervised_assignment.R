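#' Matching score of a cluster against formula disease labels
#'
#' The matching score is the highest number of member formulas sharing a
#' single disease class, divided by the cluster size: a label-purity
#' statistic in (0, 1]. A formula carrying several class labels counts
#' toward each of them; an unlabeled formula counts only in the
#' denominator (so a cluster of entirely unlabeled formulas scores 0).
#'
#' @param members character vector of formula ids in the cluster.
#' @param labels named list: formula id -> integer vector of class ids.
#' @return list with `score` and `classes` (all class ids achieving the
#'   maximal count; empty when no member is labeled).
#' @export
matching_score <- function(members, labels) {
  if (!length(members)) stop("cluster is empty")
  counts <- table(unlist(labels[members]))
  if (!length(counts)) return(list(score = 0, classes = integer(0)))
  mx <- max(counts)
  list(score = mx / length(members),
       classes = sort(as.integer(names(counts)[counts == mx])))
}

#' Assign a dominant disease class to a cluster
#'
#' The cluster qualifies iff its matching score strictly exceeds the
#' threshold AND a single class achieves the maximal member count. A tie
#' between classes voids the assignment: the cluster gives no evidence for
#' preferring one of the tied diseases.
#'
#' @param cluster a cluster record (needs `members` and `cluster_id`).
#' @param labels named list of class labels per formula id.
#' @param threshold matching-score threshold (default 0.6; strict `>`).
#' @return list with `cluster_id`, `score`, `classes`, `dominant_class`
#'   (NA when not qualified), `qualified`.
#' @export
assign_disease <- function(cluster, labels, threshold = 0.6) {
  ms <- matching_score(cluster$members, labels)
  qualified <- ms$score > threshold && length(ms$classes) == 1
  list(cluster_id = cluster$cluster_id %||% NA_character_,
       score = ms$score, classes = ms$classes,
       dominant_class = if (qualified) ms$classes else NA_integer_,
       qualified = qualified)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Highest-frequency plants of a cluster
#'
#' The frequency of a plant is the number of member formulas containing
#' it. All plants achieving the maximum are returned; an arbitrary
#' tie-break would silently discard candidate relations. Members with no
#' ingredients at all yield an empty set.
#'
#' @param members character vector of formula ids.
#' @param ds the `formula_dataset` the members come from.
#' @return character vector of plant ids (possibly length > 1, possibly
#'   empty).
#' @export
dominant_plants <- function(members, ds) {
  missing <- setdiff(members, rownames(ds$incidence))
  if (length(missing)) stop("members not in dataset: ",
                            paste(missing, collapse = ", "))
  freq <- colSums(ds$incidence[members, , drop = FALSE])
  mx <- max(freq)
  if (mx == 0) return(character(0))
  sort(names(freq)[freq == mx])
}

#' Predict (plant, disease-class) relations from a cluster set
#'
#' For every cluster whose matching score strictly exceeds the threshold
#' with a unique dominant disease, each of its highest-frequency plants is
#' predicted to be related to that disease. Predictions from different
#' clusters are pooled and deduplicated; supporting cluster ids are kept.
#'
#' @param cs a `cluster_set`, already filtered to the minimum size.
#' @param ds the `formula_dataset`.
#' @param labels named list of class labels per formula id (defaults to
#'   `ds$labels`).
#' @param threshold matching-score threshold (strict `>`; default 0.6).
#' @return list with `relations` (data.frame `plant_id`, `class_id`,
#'   `support` = comma-joined cluster ids) and `assignments` (one row per
#'   cluster: id, size, score, dominant class, qualified, plants).
#' @export
predict_relations <- function(cs, ds, labels = ds$labels, threshold = 0.6) {
  rows <- list(); arows <- list()
  for (cl in cs$clusters) {
    a <- assign_disease(cl, labels, threshold)
    plants <- if (a$qualified) dominant_plants(cl$members, ds) else character(0)
    arows[[length(arows) + 1]] <- data.frame(
      cluster_id = a$cluster_id, size = cl$size, score = a$score,
      dominant_class = if (a$qualified) a$dominant_class else NA_integer_,
      qualified = a$qualified && length(plants) > 0,
      plants = paste(plants, collapse = ","))
    if (a$qualified && length(plants))
      rows[[length(rows) + 1]] <- data.frame(
        plant_id = plants, class_id = a$dominant_class,
        cluster_id = a$cluster_id)
  }
  assignments <- if (length(arows)) do.call(rbind, arows) else
    data.frame(cluster_id = character(0), size = integer(0), score = numeric(0),
               dominant_class = integer(0), qualified = logical(0),
               plants = character(0))
  if (!length(rows)) {
    relations <- data.frame(plant_id = character(0), class_id = integer(0),
                            support = character(0))
  } else {
    flat <- do.call(rbind, rows)
    key <- paste(flat$plant_id, flat$class_id, sep = "\r")
    support <- vapply(split(flat$cluster_id, key),
                      function(s) paste(sort(unique(s)), collapse = ","),
                      character(1))
    uk <- sort(unique(key))
    parts <- strsplit(uk, "\r", fixed = TRUE)
    relations <- data.frame(
      plant_id = vapply(parts, `[[`, character(1), 1),
      class_id = as.integer(vapply(parts, `[[`, character(1), 2)),
      support = support[uk])
    relations <- relations[order(relations$class_id, relations$plant_id), ]
    rownames(relations) <- NULL
  }
  list(relations = relations, assignments = assignments)
}

#' Success rate and matching-score histogram over a threshold grid
#'
#' The success rate at a threshold t is the fraction of clusters whose
#' matching score strictly exceeds t; it is non-increasing in t. The
#' histogram bins scores into the ten half-open intervals
#' (0, 0.1], (0.1, 0.2], ..., (0.9, 1].
#'
#' @param cs a `cluster_set` (typically size-filtered).
#' @param labels named list of class labels per formula id.
#' @param thresholds numeric grid, sorted ascending (default 0.1..0.9).
#' @return list with `curve` (data.frame `threshold`, `success_rate`),
#'   `scores` (per-cluster matching scores) and `histogram` (data.frame
#'   `bin`, `count`).
#' @export
success_rate_curve <- function(cs, labels, thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  scores <- vapply(cs$clusters,
                   function(cl) matching_score(cl$members, labels)$score,
                   numeric(1))
  n <- length(scores)
  rate <- vapply(thresholds,
                 function(t) if (n == 0) NA_real_ else mean(scores > t),
                 numeric(1))
  breaks <- seq(0, 1, by = 0.1)
  cnt <- if (n) as.integer(table(cut(scores, breaks, right = TRUE))) else
    rep(0L, 10)
  list(curve = data.frame(threshold = thresholds, success_rate = rate),
       scores = scores,
       histogram = data.frame(
         bin = sprintf("(%.1f,%.1f]", breaks[-11], breaks[-1]),
         count = cnt))
}

#' Predicted-plant counts over a threshold grid
#'
#' For each threshold, re-runs the prediction and reports both the number
#' of distinct plants assigned to at least one disease class and the total
#' number of (plant, class) assignments.
#'
#' @param cs a size-filtered `cluster_set`.
#' @param ds the `formula_dataset`.
#' @param labels named list of class labels.
#' @param thresholds numeric grid.
#' @return data.frame `threshold`, `n_distinct_plants`, `n_assignments`.
#' @export
plant_count_curve <- function(cs, ds, labels = ds$labels,
                              thresholds = seq(0.1, 0.9, by = 0.1)) {
  do.call(rbind, lapply(thresholds, function(t) {
    rel <- predict_relations(cs, ds, labels, threshold = t)$relations
    data.frame(threshold = t,
               n_distinct_plants = length(unique(rel$plant_id)),
               n_assignments = nrow(rel))
  }))
}

#' How many disease classes each predicted plant is assigned to
#'
#' @param relations data.frame with columns `plant_id`, `class_id` (e.g.
#'   from [predict_relations()] or the shipped printed-prediction fixture).
#' @return list with `table` (data.frame `multiplicity`, `n_plants`),
#'   `n_plants` (distinct plants), `n_single` (assigned to exactly one
#'   class) and `n_multi` (two or more).
#' @export
plant_class_multiplicity <- function(relations) {
  if (!nrow(relations))
    return(list(table = data.frame(multiplicity = integer(0),
                                   n_plants = integer(0)),
                n_plants = 0L, n_single = 0L, n_multi = 0L))
  mult <- table(tapply(relations$class_id, relations$plant_id,
                       function(v) length(unique(v))))
  tab <- data.frame(multiplicity = as.integer(names(mult)),
                    n_plants = as.integer(mult))
  list(table = tab,
       n_plants = sum(tab$n_plants),
       n_single = sum(tab$n_plants[tab$multiplicity == 1]),
       n_multi = sum(tab$n_plants[tab$multiplicity >= 2]))
}
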
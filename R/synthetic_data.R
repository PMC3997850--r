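#' Specification of a synthetic formula corpus with planted structure
#'
#' The generator emulates the block-correlation structure the pipeline
#' exploits: formulas treating the same disease class draw from a shared
#' "signature" plant set, on top of sparse background ingredients. Each
#' class owns `signature_size` signature plants (disjoint across classes);
#' each of its `formulas_per_class` formulas includes every signature
#' plant independently with probability `p_sig` and every one of the
#' `n_background_plants` background plants with probability `p_bg`.
#' Optionally a fraction of formulas receives a second class label
#' (labels only; ingredients stay those of the first class), emulating
#' multi-indication formulas.
#'
#' @param n_classes number of disease classes D.
#' @param signature_size signature plants per class.
#' @param n_background_plants shared background plants.
#' @param formulas_per_class formulas generated per class.
#' @param p_sig per-signature-plant inclusion probability.
#' @param p_bg per-background-plant inclusion probability (`p_bg < p_sig`).
#' @param multi_label_fraction fraction of formulas given a second class.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 5, signature_size = 6,
                           n_background_plants = 50, formulas_per_class = 30,
                           p_sig = 0.8, p_bg = 0.05,
                           multi_label_fraction = 0, seed = 1) {
  if (!(p_bg >= 0 && p_bg < p_sig && p_sig <= 1))
    stop("need 0 <= p_bg < p_sig <= 1")
  if (any(c(n_classes, signature_size, n_background_plants,
            formulas_per_class) < 1))
    stop("all counts must be >= 1")
  if (multi_label_fraction < 0 || multi_label_fraction > 1)
    stop("multi_label_fraction must be in [0, 1]")
  structure(list(n_classes = as.integer(n_classes),
                 signature_size = as.integer(signature_size),
                 n_background_plants = as.integer(n_background_plants),
                 formulas_per_class = as.integer(formulas_per_class),
                 p_sig = p_sig, p_bg = p_bg,
                 multi_label_fraction = multi_label_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic formula corpus
#'
#' Deterministic per seed. Formulas that come out empty are redrawn (at
#' most 100 attempts each, then an error, to avoid a silent shift of the
#' ingredient distribution).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a `formula_dataset` with class labels) and
#'   `truth` (list: `signatures` = per-class plant sets, `labels` =
#'   per-formula class sets, `pairs` = data.frame of all planted
#'   (plant_id, class_id) relations).
#' @export
generate_formulas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  D <- spec$n_classes; s <- spec$signature_size
  B <- spec$n_background_plants; F_ <- spec$formulas_per_class
  n_plants <- D * s + B
  plant_names <- sprintf("P%03d", seq_len(n_plants))
  signatures <- lapply(seq_len(D), function(d)
    plant_names[((d - 1) * s + 1):(d * s)])
  names(signatures) <- as.character(seq_len(D))
  bg <- plant_names[(D * s + 1):n_plants]
  K <- D * F_
  ids <- sprintf("F%04d", seq_len(K))
  with_seed(spec$seed, {
    inc <- matrix(0L, K, n_plants, dimnames = list(ids, plant_names))
    primary <- rep(seq_len(D), each = F_)
    for (j in seq_len(K)) {
      d <- primary[j]
      for (attempt in seq_len(100)) {
        row <- integer(n_plants)
        row[match(signatures[[d]], plant_names)] <-
          stats::rbinom(s, 1, spec$p_sig)
        row[match(bg, plant_names)] <- stats::rbinom(B, 1, spec$p_bg)
        if (sum(row) > 0) break
        if (attempt == 100) stop("formula ", ids[j],
                                 " empty after 100 redraws; raise p_sig/p_bg")
      }
      inc[j, ] <- row
    }
    labels <- lapply(primary, function(d) d)
    if (spec$multi_label_fraction > 0) {
      extra <- which(stats::runif(K) < spec$multi_label_fraction)
      for (j in extra) {
        others <- setdiff(seq_len(D), primary[j])
        if (length(others))
          labels[[j]] <- sort(c(labels[[j]],
                                others[sample.int(length(others), 1)]))
      }
    }
    names(labels) <- ids
    ds <- formula_dataset(inc, labels)
    truth_pairs <- do.call(rbind, lapply(seq_len(D), function(d)
      data.frame(plant_id = signatures[[d]], class_id = d)))
    list(dataset = ds,
         truth = list(signatures = signatures,
                      labels = ds$labels,
                      pairs = truth_pairs))
  })
}

#' Precision and recall of predicted relations against the planted truth
#'
#' Precision is the fraction of predicted (plant, class) pairs that are
#' planted signature pairs; recall is the fraction of planted pairs that
#' were predicted. With no predictions, precision is undefined (NA) and
#' recall is 0.
#'
#' @param relations data.frame with `plant_id`, `class_id` (e.g. from
#'   [predict_relations()]).
#' @param truth the `truth` element of [generate_formulas()] output.
#' @return list with `precision`, `recall`, `n_predicted`, `n_correct`,
#'   `n_truth`.
#' @export
recovery_report <- function(relations, truth) {
  truth_key <- paste(truth$pairs$plant_id, truth$pairs$class_id)
  pred_key <- unique(paste(relations$plant_id, relations$class_id))
  n_correct <- sum(pred_key %in% truth_key)
  list(precision = if (length(pred_key)) n_correct / length(pred_key) else NA_real_,
       recall = n_correct / length(truth_key),
       n_predicted = length(pred_key),
       n_correct = n_correct,
       n_truth = length(truth_key))
}

#' Write a synthetic corpus to disk
#'
#' Writes the standard formula TSV plus a JSON file with the planted
#' truth (signature sets and labels).
#'
#' @param sim output of [generate_formulas()].
#' @param formulas_path TSV path for the formula table.
#' @param truth_path JSON path for the planted truth.
#' @return invisible NULL.
#' @export
write_synthetic <- function(sim, formulas_path, truth_path) {
  write_formulas(sim$dataset, formulas_path)
  jsonlite::write_json(
    list(signatures = sim$truth$signatures,
         labels = sim$truth$labels),
    truth_path, auto_unbox = FALSE, pretty = TRUE)
  invisible(NULL)
}
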
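#' Formula dataset: binary formula x plant incidence with disease labels
#'
#' The central container of the package. `incidence` is a K x l 0/1 integer
#' matrix whose rows are formulas (blended herbal medicines) and whose
#' columns are ingredient plants; entry (j, i) is 1 iff plant i occurs in
#' formula j. `labels` carries, for every formula, a possibly empty set of
#' disease-class ids (integers 1..18 in the shipped class table). Rows and
#' columns are kept in lexicographic id order so that every downstream
#' artifact is deterministic.
#'
#' @param incidence 0/1 matrix with unique row names (formula ids) and
#'   unique column names (plant ids).
#' @param labels named list mapping formula id to an integer vector of
#'   disease-class ids; missing formulas get an empty label set.
#' @param class_ids integer vector of admissible class ids (used to reject
#'   unknown labels); NULL skips the check.
#' @return an object of class `formula_dataset` with elements `incidence`
#'   and `labels` (aligned to the rows of `incidence`).
#' @export
formula_dataset <- function(incidence, labels = NULL, class_ids = NULL) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence must have formula ids as row names and plant ids as column names")
  if (anyDuplicated(rownames(incidence)))
    stop("duplicate formula ids in incidence matrix")
  if (anyDuplicated(colnames(incidence)))
    stop("duplicate plant ids in incidence matrix")
  if (!all(incidence %in% c(0L, 1L)))
    stop("incidence entries must be 0 or 1")
  storage.mode(incidence) <- "integer"
  incidence <- incidence[order(rownames(incidence)), order(colnames(incidence)),
                         drop = FALSE]
  if (is.null(labels)) labels <- list()
  lab <- lapply(rownames(incidence), function(f) {
    v <- labels[[f]]
    if (is.null(v)) integer(0) else sort(unique(as.integer(v)))
  })
  names(lab) <- rownames(incidence)
  if (!is.null(class_ids)) {
    bad <- setdiff(unlist(lab), as.integer(class_ids))
    if (length(bad)) stop("unknown disease-class label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(incidence = incidence, labels = lab), class = "formula_dataset")
}

#' @export
print.formula_dataset <- function(x, ...) {
  K <- nrow(x$incidence); l <- ncol(x$incidence)
  nlab <- sum(lengths(x$labels) > 0)
  cat("formula_dataset:", K, "formulas x", l, "plants;",
      nlab, "formulas carry disease labels\n")
  invisible(x)
}

#' @export
dim.formula_dataset <- function(x) dim(x$incidence)

#' Formula ids of a dataset
#' @param ds a `formula_dataset`.
#' @return character vector.
#' @export
formula_ids <- function(ds) rownames(ds$incidence)

#' Plant ids of a dataset
#' @param ds a `formula_dataset`.
#' @return character vector.
#' @export
plant_ids <- function(ds) colnames(ds$incidence)

#' Read a formula table from TSV
#'
#' Expected columns: `formula_id`, `plants` (comma-separated plant ids) and
#' optionally either `disease_entries` (comma-separated integer ids into the
#' disease-entry table, resolved through `entries`) or `class_labels`
#' (comma-separated disease-class ids, attached directly — the column
#' [write_formulas()] emits). Plant and formula ordering in the returned
#' dataset is lexicographic regardless of file order. A formula with an
#' empty ingredient list is kept with a warning; a duplicated formula id is
#' an error.
#'
#' @param path TSV file path.
#' @param entries optional disease-entry table (see [load_disease_entries()]);
#'   when supplied and the file has a `disease_entries` column, class labels
#'   are attached via [label_formulas()].
#' @return a `formula_dataset`.
#' @export
load_formulas <- function(path, entries = NULL) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("formula_id", "plants") %in% names(tab)))
    stop("formula table needs columns 'formula_id' and 'plants'")
  if (anyDuplicated(tab$formula_id))
    stop("duplicate formula id(s): ",
         paste(unique(tab$formula_id[duplicated(tab$formula_id)]), collapse = ", "))
  plant_sets <- lapply(strsplit(tab$plants, ","), function(p) {
    p <- trimws(p); p[nzchar(p)]
  })
  empty <- lengths(plant_sets) == 0
  if (any(empty))
    warning(sum(empty), " formula(s) with empty ingredient list kept: ",
            paste(tab$formula_id[empty], collapse = ", "))
  all_plants <- sort(unique(unlist(plant_sets)))
  inc <- matrix(0L, nrow(tab), length(all_plants),
                dimnames = list(tab$formula_id, all_plants))
  for (j in seq_len(nrow(tab))) inc[j, plant_sets[[j]]] <- 1L
  labels <- NULL
  if ("class_labels" %in% names(tab)) {
    labels <- lapply(strsplit(tab$class_labels, ","), function(v) {
      v <- trimws(v); as.integer(v[nzchar(v)])
    })
    names(labels) <- tab$formula_id
  }
  ds <- formula_dataset(inc, labels)
  if ("disease_entries" %in% names(tab) && !is.null(entries)) {
    ent <- lapply(strsplit(tab$disease_entries, ","), function(e) {
      e <- trimws(e); as.integer(e[nzchar(e)])
    })
    names(ent) <- tab$formula_id
    ds <- label_formulas(ds, ent, entries)
  }
  ds
}

#' Write a formula table to TSV
#'
#' Inverse of [load_formulas()]: `load_formulas(write_formulas(ds, f))`
#' reproduces the incidence matrix bit-exactly.
#'
#' @param ds a `formula_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_formulas <- function(ds, path) {
  plants <- vapply(seq_len(nrow(ds$incidence)), function(j) {
    paste(colnames(ds$incidence)[ds$incidence[j, ] == 1L], collapse = ",")
  }, character(1))
  labs <- vapply(ds$labels, function(v) paste(v, collapse = ","), character(1))
  tab <- data.frame(formula_id = rownames(ds$incidence), plants = plants,
                    class_labels = labs, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach disease-class labels via the disease-entry table
#'
#' Each formula is mapped to the union of the class ids of its disease
#' entries: a formula annotated to the entry "Common cold, dyspepsia,
#' insect bites" (classes 15, 3 and 16) receives the label set {3, 15, 16}.
#' Entries whose class set is empty (the "Fever" entry, too unspecific to
#' classify) contribute nothing, so a formula annotated only to such an
#' entry remains unclassified. The operation is idempotent: labels are
#' recomputed from `entry_labels`, not accumulated.
#'
#' @param ds a `formula_dataset`.
#' @param entry_labels named list: formula id -> integer vector of entry ids.
#' @param entries disease-entry table from [load_disease_entries()].
#' @return the dataset with `labels` replaced.
#' @export
label_formulas <- function(ds, entry_labels, entries) {
  bad <- setdiff(unlist(entry_labels), entries$entry_id)
  if (length(bad)) stop("unknown disease entry id(s): ", paste(bad, collapse = ", "))
  class_sets <- entries$class_ids
  names(class_sets) <- as.character(entries$entry_id)
  labels <- lapply(rownames(ds$incidence), function(f) {
    e <- entry_labels[[f]]
    if (is.null(e) || !length(e)) return(integer(0))
    sort(unique(unlist(class_sets[as.character(e)])))
  })
  names(labels) <- rownames(ds$incidence)
  ds$labels <- labels
  ds
}

#' Distribution of formulas over disease classes
#'
#' A formula with exactly one class label counts toward that class; one with
#' two or more counts once toward the multi-class bucket; one with none
#' counts as unclassified. Percentages are 100 * count / total rounded to
#' two decimals, half away from zero; on an empty dataset they are reported
#' as 0.
#'
#' @param ds a labeled `formula_dataset`.
#' @return list with `per_class` (data.frame: class_id, n_formulas,
#'   percentage), `multi_class_count`, `unclassified_count`, `total`, and
#'   the corresponding `multi_class_pct` / `unclassified_pct`.
#' @export
class_distribution <- function(ds) {
  nlab <- lengths(ds$labels)
  total <- length(ds$labels)
  single <- unlist(ds$labels[nlab == 1], use.names = FALSE)
  classes <- sort(unique(unlist(ds$labels)))
  counts <- vapply(classes, function(cl) sum(single == cl), integer(1))
  pct <- function(k) if (total == 0) 0 else round_half_up(100 * k / total, 2)
  list(
    per_class = data.frame(class_id = classes, n_formulas = counts,
                           percentage = vapply(counts, pct, numeric(1))),
    multi_class_count = sum(nlab >= 2),
    multi_class_pct = pct(sum(nlab >= 2)),
    unclassified_count = sum(nlab == 0),
    unclassified_pct = pct(sum(nlab == 0)),
    total = total
  )
}

#' Remove formulas from a dataset
#'
#' Used e.g. to drop formulas annotated only to a symptom too unspecific to
#' carry class information (the default pipeline drops them before network
#' construction; see [pipeline_config()]).
#'
#' @param ds a `formula_dataset`.
#' @param drop_ids character vector of formula ids to remove (may be empty).
#' @return the reduced dataset; plants are retained even if now unused, so
#'   that correlation vectors keep their length.
#' @export
exclude_formulas <- function(ds, drop_ids) {
  drop_ids <- unique(as.character(drop_ids))
  bad <- setdiff(drop_ids, rownames(ds$incidence))
  if (length(bad)) stop("unknown formula id(s): ", paste(bad, collapse = ", "))
  if (!length(drop_ids)) return(ds)
  keep <- setdiff(rownames(ds$incidence), drop_ids)
  structure(list(incidence = ds$incidence[keep, , drop = FALSE],
                 labels = ds$labels[keep]),
            class = "formula_dataset")
}

#' Load the shipped disease-entry table
#'
#' 116 disease entries (ICD-10 based) with their disease-class sets. Class
#' id 0 in the file marks an entry deliberately left unclassified and is
#' translated to an empty class set.
#'
#' @param path TSV path; defaults to the shipped fixture.
#' @return data.frame with `entry_id`, `disease`, and list-column
#'   `class_ids`.
#' @export
load_disease_entries <- function(path = jamunet_extdata("table1_disease_entries.tsv")) {
  tab <- utils::read.delim(path, colClasses = "character")
  class_ids <- lapply(strsplit(tab$class_ids, ","), function(v) {
    v <- as.integer(trimws(v))
    sort(v[v > 0L])
  })
  out <- data.frame(entry_id = as.integer(tab$entry_id), disease = tab$disease)
  out$class_ids <- class_ids
  out
}

#' Load the shipped disease-class table and corpus distribution
#'
#' 18 disease classes (16 from the NCBI disease taxonomy plus two added by
#' the study: the urinary system, and mental and behavioural disorders),
#' together with the published per-class formula counts of the corpus the
#' method was developed on, and the multi-class / unclassified buckets.
#'
#' @param path TSV path; defaults to the shipped fixture.
#' @return list with `classes` (data.frame class_id, name, source,
#'   n_formulas, percentage), `multi_class_count`, `unclassified_count`,
#'   `total`.
#' @export
load_class_distribution <- function(path = jamunet_extdata("table2_class_distribution.tsv")) {
  tab <- utils::read.delim(path, colClasses = "character")
  cls <- tab[!tab$class_id %in% c("multi", "unclassified"), ]
  classes <- data.frame(class_id = as.integer(cls$class_id), name = cls$name,
                        source = cls$source,
                        n_formulas = as.integer(cls$n_formulas),
                        percentage = suppressWarnings(as.numeric(cls$percentage)))
  list(classes = classes,
       multi_class_count = as.integer(tab$n_formulas[tab$class_id == "multi"]),
       unclassified_count = as.integer(tab$n_formulas[tab$class_id == "unclassified"]),
       total = sum(as.integer(tab$n_formulas)))
}

#' Expand a published class distribution into a labeled dataset
#'
#' Builds a minimal `formula_dataset` whose label sets realise given
#' per-class counts plus multi-class and unclassified buckets, so that
#' distribution bookkeeping can be exercised without the raw corpus (which
#' is not redistributable). The incidence matrix is a single all-ones plant
#' column; only the labels matter here.
#'
#' @param dist list as returned by [load_class_distribution()].
#' @return a `formula_dataset` with `dist$total` formulas.
#' @export
dataset_from_distribution <- function(dist) {
  counts <- dist$classes$n_formulas
  classes <- dist$classes$class_id
  labels <- c(
    unlist(lapply(seq_along(classes),
                  function(k) rep(list(classes[k]), counts[k])),
           recursive = FALSE),
    rep(list(classes[1:2]), dist$multi_class_count),
    rep(list(integer(0)), dist$unclassified_count)
  )
  n <- length(labels)
  ids <- sprintf("F%05d", seq_len(n))
  names(labels) <- ids
  inc <- matrix(1L, n, 1, dimnames = list(ids, "P1"))
  formula_dataset(inc, labels)
}
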
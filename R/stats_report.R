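# Summary statistics over competition matrices and complementation
# profiles, occurrence-association testing, and tab-separated report
# emission in the pairwise-table style (cells "m1/m2 (score)").

#' Mean competition score over cross-genus ordered pairs
#'
#' Arithmetic mean of all ordered cells whose two organisms carry
#' different genus labels.  Self pairs and same-genus pairs (duplicate
#' genome reconstructions of one genus) are excluded, so the summary is
#' not inflated by near-identical genome pairs.  Invariant under row and
#' column reordering.
#'
#' @param matrix A `competition_matrix` (square, dimnames = organism ids).
#' @param genus_of Named character vector mapping organism id -> genus.
#' @return Mean score (numeric scalar).
#' @export
mean_cross_genus_score <- function(matrix, genus_of) {
  ids <- rownames(matrix)
  if (is.null(ids) || !all(ids %in% names(genus_of))) {
    stop("genus_of must name every organism in the matrix")
  }
  g <- genus_of[ids]
  cross <- outer(g, g, `!=`)
  diag(cross) <- FALSE
  vals <- matrix[cross]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no cross-genus pairs in the matrix")
  mean(vals)
}

#' Construct an occurrence table for unordered organism pairs
#'
#' Records whether each cross-genus pair of symbionts has been observed
#' co-occurring in surveyed host individuals.
#'
#' @param a,b Character vectors of organism ids (pair members).
#' @param occurring Logical vector.
#' @return Data frame of class `occurrence_table` with canonical
#'   (sorted-within-pair) member columns.
#' @export
occurrence_table <- function(a, b, occurring) {
  stopifnot(length(a) == length(b), length(a) == length(occurring))
  lo <- pmin(a, b); hi <- pmax(a, b)
  structure(data.frame(a = lo, b = hi, occurring = as.logical(occurring),
                       stringsAsFactors = FALSE),
            class = c("occurrence_table", "data.frame"))
}

#' Read an occurrence table file
#'
#' Tab-separated with header columns `a`, `b`, `occurring` (TRUE/FALSE or
#' 1/0).
#'
#' @param path Path to the file.
#' @return An [occurrence_table()].
#' @export
load_occurrence_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  occurrence_table(d$a, d$b, d$occurring)
}

lookup_occurrence <- function(occ, a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  i <- match(paste(lo, hi), paste(occ$a, occ$b))
  occ$occurring[i]
}

#' Welch t-test of competition scores by occurrence status
#'
#' Groups the cross-genus ordered competition scores by whether the
#' unordered pair co-occurs, and applies a two-sided Welch two-sample
#' t-test (Welch-Satterthwaite degrees of freedom).
#'
#' @param matrix A `competition_matrix`.
#' @param occ An [occurrence_table()] covering every cross-genus pair.
#' @param genus_of Named character vector organism id -> genus; pairs with
#'   equal genus are excluded.
#' @return The `htest` object from [stats::t.test()].
#' @export
occurrence_association_test <- function(matrix, occ, genus_of) {
  ids <- rownames(matrix)
  g <- genus_of[ids]
  scores <- c(); flags <- c()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j || g[i] == g[j] || is.na(matrix[i, j])) next
      f <- lookup_occurrence(occ, ids[i], ids[j])
      if (is.na(f)) {
        stop("occurrence table has no entry for pair ", ids[i], " / ", ids[j])
      }
      scores <- c(scores, matrix[i, j]); flags <- c(flags, f)
    }
  }
  if (sum(flags) < 2L || sum(!flags) < 2L) {
    stop("each occurrence group needs at least 2 scores")
  }
  x <- scores[flags]
  y <- scores[!flags]
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # degenerate zero-variance groups: zero difference carries no evidence,
    # any difference is unequivocal
    d <- mean(x) - mean(y)
    return(structure(list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
                          parameter = c(df = length(x) + length(y) - 2),
                          p.value = if (d == 0) 1 else 0,
                          estimate = c(`mean of x` = mean(x),
                                       `mean of y` = mean(y)),
                          method = "Welch Two Sample t-test",
                          alternative = "two.sided",
                          data.name = "scores by occurrence"),
                     class = "htest"))
  }
  stats::t.test(x, y, var.equal = FALSE)
}

#' Read a published pairwise-interaction table
#'
#' Tab-separated with header `row_id`, `col_id`, `comp_host`, `comp_hp`,
#' `score`: for each ordered organism pair, the number of complementary
#' metabolites in the host-only and host+obligate environments (NA where
#' not applicable) and the effective-metabolic-overlap score of the column
#' organism on the row organism.  The package ships such a table for the
#' whitefly symbiont community under
#' `system.file("extdata", "whitefly_pairwise_predictions.tsv",
#' package = "symbionet")`.
#'
#' @param path Path to the table.
#' @return List with `scores` (a `competition_matrix`), `comp_host` and
#'   `comp_hp` (numeric matrices) and `organisms`.
#' @export
load_pairwise_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "NA")
  ids <- unique(c(d$row_id, d$col_id))
  mk <- function(col) {
    m <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
    m[cbind(match(d$row_id, ids), match(d$col_id, ids))] <- d[[col]]
    m
  }
  scores <- structure(mk("score"),
                      class = c("competition_matrix", "matrix"),
                      environment_basis = "optimal")
  list(scores = scores, comp_host = mk("comp_host"), comp_hp = mk("comp_hp"),
       organisms = ids)
}

#' Read an organism metadata table (id, genus, label)
#'
#' @param path Tab-separated file with header columns `organism_id`,
#'   `genus`, `label`.
#' @return Data frame; use `setNames(d$genus, d$organism_id)` as a
#'   `genus_of` map.
#' @export
load_organism_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", formatC(round(x, digits), format = "fg"))
}

#' Emit tab-separated study reports
#'
#' Writes up to four deterministic, byte-stable reports into `out_dir`:
#' \describe{
#'   \item{pairwise_interactions.tsv}{one row per ordered pair with
#'     complementary counts per environment, the competition score and the
#'     display cell `"m1/m2 (score)"` (scores rounded to 2 decimals).}
#'   \item{target_production.tsv}{organism x target binary production
#'     matrix, one block per environment.}
#'   \item{dependencies.tsv}{organism x source-metabolite losses.}
#'   \item{profile_pca.tsv}{PCA coordinates and cluster labels of the
#'     complementation profile.}
#' }
#' Missing sections are skipped; empty complementation results yield
#' zero-count cells, not missing cells.
#'
#' @param results List with any of: `competition` (a
#'   `competition_matrix`), `comp_counts` (list of environment-name ->
#'   named count matrix), `growth` (list env-name -> list of
#'   `growth_assessment` keyed by organism), `targets` (a `target_set`),
#'   `dependency` (a `dependency_table`), `pca` (output of
#'   [pca_cluster_profiles()]).
#' @param out_dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
emit_reports <- function(results, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  written <- character()
  if (!is.null(results$competition)) {
    m <- results$competition
    ids <- rownames(m)
    rows <- list()
    for (i in ids) {
      for (j in ids) {
        if (i == j) next
        ch <- chp <- 0
        if (!is.null(results$comp_counts)) {
          cc <- results$comp_counts
          ch <- if (!is.null(cc$host)) cc$host[i, j] else 0
          chp <- if (!is.null(cc$host_obligate)) cc$host_obligate[i, j] else NA
        }
        cell <- if (is.na(chp)) {
          sprintf("%s (%s)", fmt_num(ch, 0), fmt_num(m[i, j]))
        } else {
          sprintf("%s/%s (%s)", fmt_num(ch, 0), fmt_num(chp, 0),
                  fmt_num(m[i, j]))
        }
        rows[[length(rows) + 1L]] <-
          data.frame(row_id = i, col_id = j, comp_host = ch, comp_hp = chp,
                     score = m[i, j], cell = cell, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    f <- file.path(out_dir, "pairwise_interactions.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(results$growth) && !is.null(results$targets)) {
    tg <- sort(results$targets$targets)
    rows <- list()
    for (env_name in names(results$growth)) {
      ga <- results$growth[[env_name]]
      for (org in names(ga)) {
        prod <- as.integer(tg %in% ga[[org]]$produced_targets)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(environment = env_name, organism = org,
                           stringsAsFactors = FALSE),
                as.data.frame(as.list(stats::setNames(prod, tg)),
                              check.names = FALSE))
      }
    }
    tab <- do.call(rbind, rows)
    f <- file.path(out_dir, "target_production.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(results$dependency)) {
    d <- as.data.frame(unclass(results$dependency), check.names = FALSE)
    d <- cbind(organism = rownames(results$dependency), d)
    f <- file.path(out_dir, "dependencies.tsv")
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(results$pca)) {
    co <- results$pca$coordinates
    d <- data.frame(combination = rownames(co),
                    as.data.frame(co, check.names = FALSE),
                    cluster = results$pca$clusters[rownames(co)],
                    check.names = FALSE)
    f <- file.path(out_dir, "profile_pca.tsv")
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
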
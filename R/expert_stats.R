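#' The 10-stage diabetic retinopathy / maculopathy grading scale
#'
#' Stage names in scale order; the numeric code of a stage is its
#' position (1 = No DR ... 10 = ADED).
#'
#' @return Character vector of length 10.
#' @export
retinopathy_stages <- function() {
  c("No DR",
    "Mild DR without maculopathy", "Mild DR with maculopathy",
    "Moderate DR without maculopathy", "Moderate DR with maculopathy",
    "Severe DR without maculopathy", "Severe DR with maculopathy",
    "PDR without maculopathy", "PDR with maculopathy",
    "ADED")
}

#' Numeric code of a stage
#'
#' @param stage Character vector of stage names.
#' @return Integer codes 1--10.
#' @export
stage_code <- function(stage) {
  code <- match(stage, retinopathy_stages())
  if (anyNA(code))
    stop("unknown retinopathy stage(s): ",
         paste(unique(stage[is.na(code)]), collapse = ", "), call. = FALSE)
  code
}

#' Reference grading counts of the 600-image screening cohort
#'
#' `consensus_grading_counts()` returns the consensus (averaged expert)
#' diagnosis counts per stage for a 600-image hospital screening cohort
#' graded on the 10-stage scale; `expert_grading_counts()` returns the
#' per-expert 10 x 3 count table for the same images (1800 gradings,
#' 600 per expert). These printed tables are the inputs to the grading
#' analytics and to the binary maculopathy label split.
#'
#' @return A named integer vector (consensus) or an integer matrix with
#'   stages as rows and experts as columns.
#' @export
consensus_grading_counts <- function() {
  setNames(c(276L, 72L, 27L, 85L, 83L, 23L, 11L, 6L, 10L, 7L),
           retinopathy_stages())
}

#' @rdname consensus_grading_counts
#' @export
expert_grading_counts <- function() {
  m <- cbind(expert1 = c(326L, 55L, 21L, 79L, 90L, 5L, 3L, 6L, 8L, 7L),
             expert2 = c(267L, 58L, 12L, 90L, 127L, 6L, 6L, 9L, 20L, 5L),
             expert3 = c(314L, 14L, 31L, 43L, 143L, 0L, 19L, 2L, 25L, 9L))
  rownames(m) <- retinopathy_stages()
  m
}

#' Expand a stage-by-expert count table into a grading table
#'
#' @param counts Integer matrix, stages (all 10, in scale order) by
#'   experts.
#' @return A grading table: data frame with `image_id`, `expert_id`,
#'   `stage` (one row per grading; image ids are synthetic, numbered
#'   within expert).
#' @export
expand_grading_counts <- function(counts) {
  stages <- retinopathy_stages()
  if (is.null(rownames(counts))) rownames(counts) <- stages
  stopifnot(identical(rownames(counts), stages))
  experts <- colnames(counts)
  if (is.null(experts)) experts <- paste0("expert", seq_len(ncol(counts)))
  rows <- lapply(seq_along(experts), function(e) {
    stage <- rep(stages, counts[, e])
    data.frame(image_id = sprintf("img%04d", seq_along(stage)),
               expert_id = experts[e], stage = stage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write grading tables
#'
#' CSV layout: columns `image_id`, `expert_id`, `stage` (stage names on
#' the 10-stage scale).
#'
#' @param path CSV path.
#' @param tbl Grading table data frame.
#' @return `read_grading_table()` returns the validated data frame.
#' @export
read_grading_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "expert_id", "stage")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("grading table misses columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stage_code(df$stage)   # validates
  if (anyDuplicated(df[c("image_id", "expert_id")]))
    stop("more than one grade for an (image, expert) pair", call. = FALSE)
  df
}

#' @rdname read_grading_table
#' @export
write_grading_table <- function(tbl, path) {
  write.csv(tbl[c("image_id", "expert_id", "stage")], path,
            row.names = FALSE)
  invisible(path)
}

#' Pooled mean and standard deviation of the coded labels
#'
#' Stage labels coded 1--10 are pooled over all experts; the mean and
#' sample standard deviation (n - 1) summarise the grade distribution
#' of the whole grading table.
#'
#' @param tbl Grading table (`image_id`, `expert_id`, `stage`).
#' @return List with `mean` and `sd`, in grade units.
#' @export
pooled_label_stats <- function(tbl) {
  if (nrow(tbl) == 0L) stop("empty grading table", call. = FALSE)
  code <- stage_code(tbl$stage)
  list(mean = mean(code), sd = sd(code))
}

#' Categorise a stage under one of three schemes
#'
#' Scheme I collapses to No DR vs DR; scheme II to No DR,
#' non-proliferative DR (mild/moderate/severe), proliferative DR and
#' ADED; scheme III is the identity (all 10 stages).
#'
#' @param stage Character vector of stage names.
#' @param scheme `"I"`, `"II"` or `"III"`.
#' @return Character vector of category names.
#' @export
categorise <- function(stage, scheme = c("I", "II", "III")) {
  scheme <- match.arg(scheme)
  code <- stage_code(stage)
  switch(scheme,
    I = ifelse(code == 1L, "No DR", "DR"),
    II = c("No DR", rep("Non-proliferative DR", 6L),
           rep("Proliferative DR", 2L), "ADED")[code],
    III = stage)
}

#' Five-number summary of one expert's grades
#'
#' Tukey's five numbers (minimum, lower hinge, median, upper hinge,
#' maximum; hinges by the median-of-halves rule) of the coded labels of
#' one expert, matching the statistics a boxplot displays.
#'
#' @param tbl Grading table.
#' @param expert Expert id present in `tbl$expert_id`.
#' @return Named numeric vector `min`, `q1`, `median`, `q3`, `max`.
#' @export
five_number_summary <- function(tbl, expert) {
  sel <- tbl$expert_id == expert
  if (!any(sel)) stop("unknown expert: ", expert, call. = FALSE)
  setNames(fivenum(stage_code(tbl$stage[sel])),
           c("min", "q1", "median", "q3", "max"))
}

#' Stage-by-expert crosstab with a chi-square test of independence
#'
#' Tabulates grades by expert (all 10 stages, scale order), computes
#' column percentages (one decimal), and runs Pearson's chi-square test
#' of independence. Rows or columns with a zero margin are dropped with
#' a warning before the test (the expected counts would be zero).
#'
#' @param tbl Grading table with at least two experts.
#' @return List with `counts` (10 x E), `percent` (column percentages,
#'   1 dp), `chi2`, `df` and `p`.
#' @export
crosstab_chi_square <- function(tbl) {
  experts <- unique(tbl$expert_id)
  if (length(experts) < 2L) stop("need >= 2 experts", call. = FALSE)
  counts <- table(factor(tbl$stage, levels = retinopathy_stages()),
                  factor(tbl$expert_id, levels = experts))
  pct <- round(100 * prop.table(counts, margin = 2), 1)
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c))
    warning("dropping zero-margin rows/columns before the chi-square test")
  test_tab <- counts[keep_r, keep_c, drop = FALSE]
  if (any(dim(test_tab) < 2L))
    stop("need >= 2 non-empty stages and experts", call. = FALSE)
  ct <- suppressWarnings(chisq.test(test_tab, correct = FALSE))
  list(counts = unclass(counts), percent = unclass(pct),
       chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' One-way ANOVA of coded grades across experts
#'
#' Tests whether the mean coded grade differs between experts, followed
#' by Bonferroni-adjusted pairwise comparisons (pooled-variance t
#' tests; adjusted p values are capped at 1).
#'
#' @param tbl Grading table with at least two experts, each with at
#'   least two gradings.
#' @return List with `p_overall`, `f_statistic` and `pairwise` (a
#'   symmetric matrix of adjusted p values, `NA` on the diagonal).
#' @export
one_way_anova <- function(tbl) {
  code <- stage_code(tbl$stage)
  expert <- factor(tbl$expert_id)
  if (nlevels(expert) < 2L) stop("need >= 2 experts", call. = FALSE)
  if (any(table(expert) < 2L))
    stop("every expert needs >= 2 gradings", call. = FALSE)
  fit <- aov(code ~ expert)
  s <- summary(fit)[[1]]
  pw <- pairwise.t.test(code, expert, p.adjust.method = "bonferroni",
                        pool.sd = TRUE)
  ## symmetrise the lower-triangular result
  lev <- levels(expert)
  mat <- matrix(NA_real_, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (i in rownames(pw$p.value)) for (j in colnames(pw$p.value)) {
    v <- pw$p.value[i, j]
    if (!is.na(v)) { mat[i, j] <- v; mat[j, i] <- v }
  }
  list(p_overall = s[["Pr(>F)"]][1], f_statistic = s[["F value"]][1],
       pairwise = mat)
}
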
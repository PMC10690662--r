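#' The 18 bilateral cortical region codes
#'
#' Canonical short codes for the 18 cortical labels used to localize the
#' resection zone and the detected clusters, each existing in a left and
#' right variant (36 region codes such as `"AML_R"`).
#'
#' @return Character vector of the 18 short codes.
#' @export
region_codes <- function() {
  c("VMPF",  # ventral medial prefrontal
    "MDPF",  # medial dorsal prefrontal
    "VLPF",  # lateral ventral (ventrolateral) prefrontal
    "DLPF",  # lateral dorsal prefrontal
    "MP",    # medial premotor
    "LPr",   # lateral premotor
    "MC",    # medial central
    "LC",    # lateral central
    "AML",   # anterior medial temporal
    "ATL",   # anterior lateral temporal
    "PMT",   # posterior medial temporal
    "PLT",   # posterior lateral temporal
    "MPa",   # medial parietal
    "LP",    # lateral parietal
    "MO",    # medial occipital
    "LO",    # lateral occipital
    "OI",    # operculo-insular
    "TPO")   # temporo-parieto-occipital junction
}

all_region_codes <- function()
  c(paste0(region_codes(), "_L"), paste0(region_codes(), "_R"))

#' Parse a region-set string
#'
#' Parses the compact dialect used in the cohort table: codes separated by
#' `"+"`, with a trailing hemisphere letter that distributes over the
#' preceding run of codes (`"AML + ATL R"` is \{AML_R, ATL_R\}); tokens may
#' also carry their own hemisphere (`"AML L + ATL L + ATL R"`); `"N"` (or an
#' empty string) is the empty set.
#'
#' @param text the region-set string.
#' @return Character vector of `CODE_H` region codes (possibly empty).
#' @export
parse_region_set <- function(text) {
  text <- trimws(text)
  if (is.na(text) || text == "" || toupper(text) == "N") return(character())
  toks <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  valid <- region_codes()
  out <- character(); pending <- character()
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([A-Za-z]+?)\\s*([LR])?$", tok))[[1]]
    if (length(m) == 0L || m[2] == "")
      stop("cannot parse region token: '", tok, "'")
    code <- m[2]; hemi <- m[3]
    # a bare trailing L/R glued to the code (e.g. "VLPFR") is not split:
    # codes are matched exactly against the canonical list
    if (!code %in% valid) {
      # try stripping a trailing hemisphere letter fused to the code
      tail1 <- substr(code, nchar(code), nchar(code))
      head1 <- substr(code, 1, nchar(code) - 1)
      if (hemi == "" && tail1 %in% c("L", "R") && head1 %in% valid) {
        code <- head1; hemi <- tail1
      } else stop("unknown region code: '", code, "'")
    }
    if (hemi == "") {
      pending <- c(pending, code)
    } else {
      out <- c(out, paste0(c(pending, code), "_", hemi))
      pending <- character()
    }
  }
  if (length(pending))
    stop("region codes without a hemisphere: ", paste(pending, collapse = ", "))
  unique(out)
}

#' Format a region set back to the compact dialect
#'
#' Inverse of [parse_region_set()] up to set equality: groups codes by
#' hemisphere and emits `"CODE1 + CODE2 H"` runs; the empty set is `"N"`.
#'
#' @param set character vector of `CODE_H` codes.
#' @return A single string.
#' @export
format_region_set <- function(set) {
  if (length(set) == 0L) return("N")
  hemi <- sub("^.*_", "", set)
  code <- sub("_[LR]$", "", set)
  parts <- vapply(unique(hemi), function(h)
    paste(paste(code[hemi == h], collapse = " + "), h), "")
  paste(parts, collapse = " + ")
}

#' Load the packaged surgical-cohort fixture
#'
#' Reads the per-patient table bundled with the package (20 operated
#' drug-resistant epilepsy patients): demographics, MRI status, lobar
#' localisation, Engel outcome class, and the region sets found by SEEG,
#' surgery (the resection zone), visual PET reading, SPM and the subtraction
#' method.  A surgery entry of `"Idem"` resolves to the SEEG set.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A `sipcom_cohort` data.frame with parsed list-columns `rz`,
#'   `seeg_set`, `visual_set`, `spm_set`, `sipcom_set`, plus `engel_good` and
#'   `mri_negative` logicals.
#' @export
load_cohort_fixture <- function(path = system.file("extdata", "cohort_fixture.csv",
                                                   package = "sipcom")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$seeg_set <- lapply(df$seeg, parse_region_set)
  df$rz <- lapply(seq_len(nrow(df)), function(i)
    if (trimws(df$surgery[i]) == "Idem") df$seeg_set[[i]]
    else parse_region_set(df$surgery[i]))
  if (any(lengths(df$rz) == 0L)) stop("fixture has an empty resection zone")
  df$visual_set <- lapply(df$visual, parse_region_set)
  df$spm_set <- lapply(df$spm, parse_region_set)
  df$sipcom_set <- lapply(df$sipcom, parse_region_set)
  df$engel_good <- grepl("^[12]", df$engel_class)
  df$mri_negative <- df$mri_status == "negative"
  class(df) <- c("sipcom_cohort", "data.frame")
  df
}

#' Patient-level concordance of a method with the resection zone
#'
#' A detection is concordant when the method's region set intersects the
#' resection-zone region set ("a true hypometabolic cluster is one whose
#' localisation matches the resected cortex").
#'
#' @param record one cohort row (data.frame of one row or list) with `rz`
#'   and the method's region-set column.
#' @param method `"visual"`, `"spm"` or `"sipcom"`.
#' @return TRUE/FALSE.
#' @export
patient_concordant <- function(record, method = c("sipcom", "spm", "visual")) {
  method <- match.arg(method)
  rz <- record$rz; ms <- record[[paste0(method, "_set")]]
  if (is.list(rz) && length(rz) == 1L) rz <- rz[[1]]
  if (is.list(ms) && length(ms) == 1L) ms <- ms[[1]]
  length(intersect(ms, rz)) > 0L
}

resolve_subset <- function(cohort, subset) {
  if (is.null(subset)) return(rep(TRUE, nrow(cohort)))
  if (is.logical(subset)) return(subset)
  if (is.function(subset))
    return(vapply(seq_len(nrow(cohort)), function(i) isTRUE(subset(cohort[i, ])), NA))
  switch(match.arg(subset, c("engel_good", "engel_poor", "mri_positive",
                             "mri_negative")),
         engel_good = cohort$engel_good,
         engel_poor = !cohort$engel_good,
         mri_positive = !cohort$mri_negative,
         mri_negative = cohort$mri_negative)
}

#' Cohort-level detection rate of a method
#'
#' Fraction of patients (optionally within a subgroup) whose method region
#' set is concordant with the resection zone.
#'
#' @param cohort a `sipcom_cohort`.
#' @param method `"visual"`, `"spm"` or `"sipcom"`.
#' @param subset NULL (whole cohort), a logical vector, a predicate
#'   `function(record)`, or one of `"engel_good"`, `"engel_poor"`,
#'   `"mri_positive"`, `"mri_negative"`.
#' @return List with `count`, `n`, `rate` (= count / n).
#' @export
cohort_rates <- function(cohort, method = c("sipcom", "spm", "visual"),
                         subset = NULL) {
  method <- match.arg(method)
  sel <- resolve_subset(cohort, subset)
  if (!any(sel)) stop("empty subgroup")
  sub <- cohort[sel, , drop = FALSE]
  hits <- vapply(seq_len(nrow(sub)), function(i)
    patient_concordant(sub[i, ], method), NA)
  list(count = sum(hits), n = nrow(sub), rate = sum(hits) / nrow(sub))
}

#' Micro-averaged region-level recall and precision
#'
#' Under this package's definition (reported values depend strongly on the
#' definition, which published summaries rarely spell out): recall =
#' sum over patients of |method regions intersect RZ regions| divided by the
#' summed RZ set size; precision = the same numerator divided by the summed
#' method set size (NA when every method set is empty).
#'
#' @inheritParams cohort_rates
#' @return List with `recall`, `precision`, `definition`.
#' @export
region_recall_precision <- function(cohort, method = c("sipcom", "spm", "visual")) {
  method <- match.arg(method)
  col <- paste0(method, "_set")
  inter <- vapply(seq_len(nrow(cohort)), function(i)
    length(intersect(cohort[[col]][[i]], cohort$rz[[i]])), 0L)
  n_rz <- sum(lengths(cohort$rz))
  n_m <- sum(lengths(cohort[[col]]))
  list(recall = sum(inter) / n_rz,
       precision = if (n_m == 0L) NA_real_ else sum(inter) / n_m,
       definition = "micro-averaged over patients: sum|method & RZ| / sum|RZ| (recall), / sum|method| (precision)")
}

#' Attach atlas regions to detected clusters
#'
#' For each cluster, lists every atlas region whose overlap fraction (shared
#' voxels / cluster voxels) exceeds `min_fraction` (default: any overlap).
#'
#' @param clusters a `sipcom_clusters` table (with voxel memberships).
#' @param atlas integer label array on the same lattice as the Z-map.
#' @param atlas_table data.frame with `label_id`, `region_code`, `hemisphere`.
#' @param min_fraction minimum overlap fraction (default 0 = any overlap).
#' @return The cluster table with `regions` and `overlap_fractions` columns
#'   (`" + "`-separated strings) and a `region_sets` list attribute.
#' @export
assign_cluster_regions <- function(clusters, atlas, atlas_table,
                                   min_fraction = 0) {
  stopifnot(inherits(clusters, "sipcom_clusters"))
  geom <- attr(clusters, "geometry")
  if (!identical(dim(atlas), geom$dim))
    stop("atlas is not on the Z-map lattice: ",
         paste(dim(atlas), collapse = "x"), " vs ",
         paste(geom$dim, collapse = "x"))
  vox <- attr(clusters, "voxels")
  code_of <- stats::setNames(paste0(atlas_table$region_code, "_",
                                    atlas_table$hemisphere),
                             atlas_table$label_id)
  sets <- vector("list", nrow(clusters))
  regions <- fracs <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    labs <- atlas[vox[[i]]]
    tl <- table(labs[labs > 0])
    fr <- as.numeric(tl) / length(vox[[i]])
    keep <- fr > min_fraction
    if (!any(keep)) {
      warning("cluster ", clusters$cluster_id[i], " lies outside atlas labels")
      sets[[i]] <- character(); regions[i] <- ""; fracs[i] <- ""
    } else {
      ord <- order(-fr[keep])
      ids <- names(tl)[keep][ord]
      sets[[i]] <- unname(code_of[ids])
      regions[i] <- paste(code_of[ids], collapse = " + ")
      fracs[i] <- paste(sprintf("%.3f", fr[keep][ord]), collapse = " + ")
    }
  }
  clusters$regions <- regions
  clusters$overlap_fractions <- fracs
  attr(clusters, "region_sets") <- sets
  clusters
}

#' Summarize false-positive cluster counts over lesion-free subjects
#'
#' @param tables list of `sipcom_clusters` tables (or a numeric vector of
#'   per-subject cluster counts).
#' @return List with `mean`, `sd` (sample SD; 0 with `n1_flag` when a single
#'   subject), `range`, `n`, `counts`.
#' @export
score_control_fp <- function(tables) {
  counts <- if (is.numeric(tables)) tables
  else vapply(tables, NROW, 0L)
  if (length(counts) < 1L) stop("need at least one subject")
  list(mean = mean(counts),
       sd = if (length(counts) > 1L) stats::sd(counts) else 0,
       range = range(counts), n = length(counts),
       n1_flag = length(counts) == 1L,
       counts = as.numeric(counts))
}

#' Full cohort evaluation report
#'
#' Patient-level detection rates for each method on the whole cohort and the
#' Engel and MRI subgroups, plus the micro-averaged region-level
#' recall/precision.
#'
#' @param cohort a `sipcom_cohort` (default: the packaged fixture).
#' @return A `sipcom_evaluation` list of rate tables.
#' @export
evaluate_cohort <- function(cohort = load_cohort_fixture()) {
  methods <- c("sipcom", "spm", "visual")
  groups <- list(all = NULL, engel_good = "engel_good", engel_poor = "engel_poor",
                 mri_positive = "mri_positive", mri_negative = "mri_negative")
  rates <- do.call(rbind, lapply(names(groups), function(g)
    do.call(rbind, lapply(methods, function(m) {
      r <- cohort_rates(cohort, m, groups[[g]])
      data.frame(group = g, method = m, count = r$count, n = r$n,
                 rate = r$rate, percent = 100 * r$rate)
    }))))
  rp <- do.call(rbind, lapply(methods, function(m) {
    x <- region_recall_precision(cohort, m)
    data.frame(method = m, recall = x$recall, precision = x$precision)
  }))
  structure(list(rates = rates, region_recall_precision = rp,
                 n = nrow(cohort)), class = "sipcom_evaluation")
}

#' @export
print.sipcom_evaluation <- function(x, ...) {
  cat(sprintf("<sipcom_evaluation> %d patients\n", x$n))
  print(x$rates, row.names = FALSE, digits = 3)
  cat("region-level (micro-averaged):\n")
  print(x$region_recall_precision, row.names = FALSE, digits = 3)
  invisible(x)
}
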
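# ---- cohort table IO -------------------------------------------------------
# All delimited outputs carry a single provenance comment line
# ("# epimediate <version> config=<hash>") above the header; readers skip it.
# Delimiter on read is auto-detected by data.table::fread.

prov_line <- function(config_hash = "none")
  sprintf("# epimediate %s config=%s",
          as.character(utils::packageVersion("epimediate")), config_hash)

write_table_prov <- function(d, path, config_hash = "none", sep = "\t",
                             col.names = TRUE) {
  con <- file(path, "w")
  writeLines(prov_line(config_hash), con)
  close(con)
  data.table::fwrite(d, path, sep = sep, append = TRUE,
                     col.names = col.names, quote = FALSE)
  invisible(path)
}

read_table_prov <- function(path, header = TRUE) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  as.data.frame(data.table::fread(path, header = header, skip = skip,
                                  data.table = FALSE, sep = "auto"))
}

#' Write a simulated (or assembled) cohort bundle to disk
#'
#' Emits the on-disk form of every component: beta matrix as TSV in
#' probes x samples orientation (450K convention; probe id first column),
#' probe annotation, phenotype table, one exposure TSV per exam, FAM-style
#' pedigree (fam, id, father, mother, sex; 0 = missing parent, no header),
#' the truth table when present, and a YAML config echo.
#'
#' @param bundle a `cohort_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- object_hash(bundle$config %||% "unspecified")
  meth_dt <- data.table::data.table(probe_id = colnames(bundle$methylation),
                                    t(bundle$methylation))
  write_table_prov(meth_dt, file.path(dir, "methylation.tsv"), h)
  write_table_prov(bundle$annotation, file.path(dir, "annotation.tsv"), h)
  write_table_prov(bundle$phenotypes, file.path(dir, "phenotypes.tsv"), h)
  for (ex in names(bundle$exposures)) {
    d <- data.table::data.table(sample_id = rownames(bundle$exposures[[ex]]),
                                bundle$exposures[[ex]])
    write_table_prov(d, file.path(dir, sprintf("exposures_%s.tsv", ex)), h)
  }
  utils::write.table(bundle$pedigree[, c("fam", "id", "father", "mother", "sex")],
                     file.path(dir, "pedigree.fam"),
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(bundle$truth))
    write_table_prov(bundle$truth, file.path(dir, "truth.tsv"), h)
  if (!is.null(bundle$expression)) {
    d <- data.table::data.table(sample_id = rownames(bundle$expression),
                                as.data.frame(bundle$expression))
    write_table_prov(d, file.path(dir, "expression.tsv"), h)
  }
  if (!is.null(bundle$config))
    yaml::write_yaml(config_as_yaml(bundle$config),
                     file.path(dir, "config_echo.yaml"))
  invisible(dir)
}

config_as_yaml <- function(cfg) {
  x <- unclass(cfg)
  x$mediators <- as.list(as.data.frame(x$mediators))
  x$family_size <- as.list(x$family_size)
  x
}

#' Read a FAM-style pedigree file
#'
#' @param path whitespace-delimited file with columns fam, id, father,
#'   mother, sex and no header; "0" codes a missing parent
#' @return pedigree data.frame
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("fam", "id", "father", "mother", "sex"))
  ped$sex <- as.integer(ped$sex)
  class(ped) <- c("pedigree_df", "data.frame")
  ped
}

#' Load a cohort bundle from disk
#'
#' Reads every table written by [write_cohort()] (or equivalently formatted
#' external files), aligns all components on the intersection of sample ids
#' in deterministic lexicographic order, and derives the kinship matrix from
#' the pedigree. Samples missing from any mandatory component are dropped
#' with a message stating the count.
#'
#' @param paths named list with entries `methylation`, `annotation`,
#'   `phenotypes`, `exposures` (named character vector, one file per exam),
#'   `pedigree`, and optional `expression`, `truth`
#' @return a `cohort_bundle`
#' @export
load_bundle <- function(paths) {
  need <- c("methylation", "annotation", "phenotypes", "exposures", "pedigree")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing paths: ", paste(miss, collapse = ", "))
  for (p in c(paths$methylation, paths$annotation, paths$phenotypes,
              unlist(paths$exposures), paths$pedigree))
    if (!file.exists(p)) stop("file not found: ", p)

  md <- read_table_prov(paths$methylation)
  probe_ids <- md[[1]]
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids in beta matrix")
  meth <- t(as.matrix(md[, -1, drop = FALSE]))  # samples x probes in memory
  colnames(meth) <- probe_ids
  if (anyDuplicated(rownames(meth)))
    stop("duplicate sample ids in beta matrix")

  ann <- read_table_prov(paths$annotation)
  ann$chromosome <- as.character(ann$chromosome)
  validate_annotation(ann)

  phen <- read_table_prov(paths$phenotypes)
  if (anyDuplicated(phen$sample_id))
    stop("duplicate sample ids in phenotype table")

  ped <- read_pedigree(paths$pedigree)
  expo <- lapply(paths$exposures, function(p) {
    d <- read_table_prov(p)
    if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in ", p)
    rownames(d) <- d$sample_id
    d[, -1, drop = FALSE]
  })
  names(expo) <- names(paths$exposures)

  ids <- Reduce(intersect, c(list(rownames(meth), phen$sample_id, ped$id),
                             lapply(expo, rownames)))
  ids <- sort(ids)
  if (!length(ids)) stop("no overlapping samples across components")
  n_all <- length(unique(c(rownames(meth), phen$sample_id)))
  dropped <- n_all - length(ids)
  if (dropped > 0)
    message(sprintf("load_bundle: dropped %d sample(s) missing from >=1 component",
                    dropped))

  ped <- ped[ped$id %in% ids | ped$id %in% c(ped$father, ped$mother), , drop = FALSE]
  kin_full <- kinship_from_pedigree(ped)
  kin <- unclass(kin_full)[ids, ids]
  attr(kin, "family") <- attr(kin_full, "family")[ids]
  class(kin) <- c("kinship_matrix", "matrix")

  bundle <- list(
    methylation = meth[ids, , drop = FALSE],
    annotation = ann,
    phenotypes = phen[match(ids, phen$sample_id), , drop = FALSE],
    exposures = structure(lapply(expo, function(d) d[ids, , drop = FALSE]),
                          exams = names(expo), sample_id = ids,
                          class = "exposure_panel"),
    kinship = kin,
    pedigree = ped)
  if (!is.null(paths$truth) && file.exists(paths$truth))
    bundle$truth <- read_table_prov(paths$truth)
  if (!is.null(paths$expression) && file.exists(paths$expression)) {
    d <- read_table_prov(paths$expression)
    ex <- as.matrix(d[, -1, drop = FALSE])
    rownames(ex) <- d$sample_id
    common <- intersect(ids, rownames(ex))
    bundle$expression <- ex[common, , drop = FALSE]
  }
  class(bundle) <- "cohort_bundle"
  bundle
}

GENIC_REGIONS <- c("TSS1500", "5UTR", "genic", "3UTR", "intergenic")
CPG_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                   "OpenSea")

validate_annotation <- function(ann) {
  need <- c("probe_id", "chromosome", "position", "gene", "genic_region",
            "cpg_relation")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe ids in annotation")
  if (any(ann$position < 1)) stop("annotation positions must be >= 1")
  bad <- setdiff(unique(ann$genic_region), GENIC_REGIONS)
  if (length(bad)) stop("unknown genic_region value(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(ann$cpg_relation), CPG_RELATIONS)
  if (length(bad)) stop("unknown cpg_relation value(s): ",
                        paste(bad, collapse = ", "))
  invisible(ann)
}

#' Look up one probe's annotation record
#'
#' @param probe_id CpG probe id
#' @param ann annotation data.frame
#' @return one-row data.frame (probe_id, chromosome, position, gene,
#'   genic_region, cpg_relation)
#' @export
annotate_probe <- function(probe_id, ann) {
  i <- match(probe_id, ann$probe_id)
  if (is.na(i)) stop("probe not found in annotation: ", probe_id)
  rec <- ann[i, , drop = FALSE]
  if (rec$gene == "" && rec$genic_region != "intergenic")
    rec$genic_region <- "intergenic"
  rownames(rec) <- NULL
  rec
}

#' Packaged annotation of known TG-associated 450K probes
#'
#' @return annotation data.frame for 28 CpG probes reported as associated
#'   with plasma triglyceride (GRCh37/hg19, 1-based positions)
#' @export
tg_probe_annotation <- function() {
  path <- system.file("extdata", "tg_probe_annotation.tsv",
                      package = "epimediate")
  ann <- read_table_prov(path)
  ann$chromosome <- as.character(ann$chromosome)
  ann
}
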
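# File formats: VCF (via vcfR) or plain dosage matrix + positions sidecar for
# genotypes; TSV phenotypes; BED-like region lists (0-based half-open);
# square whitespace relationship matrix with a one-line ID header.

#' Read region definitions (BED-like)
#'
#' Reads a whitespace-delimited gene list with columns chrom, start, end and
#' (optionally) name. Coordinates follow the BED convention: 0-based,
#' half-open.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_regions <- function(path) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(bed) < 3L) stop("region file needs at least chrom, start, end")
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$name <- if (ncol(bed) >= 4L) as.character(bed[[4L]]) else
    sprintf("%s:%d-%d", bed$chrom, bed$start, bed$end)
  bed <- bed[, c("chrom", "start", "end", "name")]
  if (any(bed$start >= bed$end))
    stop("invalid region(s): start must be < end (BED, 0-based half-open)")
  bed
}

#' Read genotypes for one region
#'
#' Two sources are supported. A VCF file: biallelic SNVs only (multi-allelic
#' records are skipped with a warning), dosages taken from the GT field as
#' ALT-allele counts; sites are restricted to `region` (BED half-open
#' interval on the 1-based VCF positions). Or a plain whitespace dosage
#' matrix (first column sample ID, one column per variant) with a positions
#' sidecar file (columns `chrom`, `pos`, one row per variant, same order).
#'
#' Re-polarisation to minor-allele counts, mean-imputation of missing
#' dosages and removal of monomorphic sites happen in [region_genotypes()].
#'
#' @param path VCF path or dosage-matrix path.
#' @param positions_path sidecar path (matrix input only).
#' @param region optional single-row region definition (see [read_regions()]).
#' @param sample_ids optional IDs to subset/reorder to; an error is raised if
#'   none overlap.
#' @return A [region_genotypes()] object.
#' @export
read_genotypes <- function(path, positions_path = NULL, region = NULL,
                           sample_ids = NULL) {
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)
  if (is_vcf) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(v)
    if (any(!bi)) {
      warning(sum(!bi), " multi-allelic site(s) skipped", call. = FALSE)
      v <- v[bi, ]
    }
    pos <- as.integer(vcfR::getPOS(v))
    chrom <- vcfR::getCHROM(v)
    keep <- rep(TRUE, length(pos))
    rid <- NULL
    if (!is.null(region)) {
      keep <- chrom == region$chrom & pos > region$start & pos <= region$end
      rid <- region$name
    }
    if (!any(keep)) stop("zero variants in region")
    gt <- vcfR::extract.gt(v[keep, ], element = "GT")
    g <- gsub("\\|", "/", gt)
    dos <- rep(NA_real_, length(g))
    dos[g == "0/0"] <- 0
    dos[g %in% c("0/1", "1/0")] <- 1
    dos[g == "1/1"] <- 2
    G <- t(matrix(dos, nrow = nrow(gt)))   # samples x variants
    ids <- colnames(gt)
    pos <- pos[keep]
  } else {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    G <- as.matrix(tab[, -1L, drop = FALSE])
    if (is.null(positions_path))
      stop("matrix genotype input requires a positions sidecar file")
    ps <- utils::read.table(positions_path, header = FALSE,
                            stringsAsFactors = FALSE)
    pos <- as.numeric(ps[[ncol(ps)]])
    chrom <- if (ncol(ps) >= 2L) as.character(ps[[1L]]) else
      rep(".", length(pos))
    if (length(pos) != ncol(G))
      stop("positions sidecar does not match the number of variant columns")
    rid <- NULL
    if (!is.null(region)) {
      keep <- chrom == region$chrom & pos > region$start & pos <= region$end
      if (!any(keep)) stop("zero variants in region")
      G <- G[, keep, drop = FALSE]
      pos <- pos[keep]
      rid <- region$name
    }
  }
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, ids)
    if (all(is.na(idx)))
      stop("no genotype samples overlap the requested sample ids")
    if (anyNA(idx))
      stop(sum(is.na(idx)), " requested sample id(s) missing from genotypes")
    G <- G[idx, , drop = FALSE]
    ids <- sample_ids
  }
  region_genotypes(G, pos, ids = ids, region_id = rid)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated table with a header; rows with missing trait or covariate
#' values are dropped (with a message of the count) and an intercept column
#' is prepended to the covariate design.
#'
#' @param path TSV path.
#' @param trait trait column name.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param id_col sample-ID column name or index (default: first column).
#' @return A [phenotype_data()] object.
#' @export
read_phenotypes <- function(path, trait, covariates = character(0),
                            id_col = 1L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(trait, covariates)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("column(s) not found: ", paste(miss, collapse = ", "))
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) stop("sample ids are not unique")
  y <- as.numeric(tab[[trait]])
  C <- if (length(covariates))
    as.matrix(tab[, covariates, drop = FALSE]) else NULL
  complete <- !is.na(y)
  if (!is.null(C)) complete <- complete & stats::complete.cases(C)
  if (sum(complete) < 2L) stop("fewer than 2 complete phenotype rows")
  if (any(!complete))
    message(sum(!complete), " row(s) with missing trait/covariates dropped")
  phenotype_data(y[complete],
                 if (!is.null(C)) C[complete, , drop = FALSE],
                 ids = ids[complete])
}

#' Read a relationship matrix
#'
#' Square whitespace-delimited matrix whose first line is a header of sample
#' IDs, in the same order as the rows.
#'
#' @param path file path.
#' @return Symmetric numeric matrix with ID dimnames.
#' @export
read_kinship <- function(path) {
  ids <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  R <- as.matrix(utils::read.table(path, header = FALSE, skip = 1L))
  if (nrow(R) != length(ids) || ncol(R) != length(ids))
    stop("relationship matrix is not square against its ID header")
  dimnames(R) <- list(ids, ids)
  if (max(abs(R - t(R))) > 1e-10)
    stop("relationship matrix is not symmetric")
  R
}

#' Write a relationship matrix
#'
#' @param R matrix with ID dimnames.
#' @param path output path.
#' @export
write_kinship <- function(R, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(R), collapse = " "), con)
  utils::write.table(format(R, digits = 10, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Write association results as TSV
#'
#' Stable column order; P values in full-precision scientific notation;
#' configuration echoed as `#` header comments. Rerunning with the same
#' inputs produces a byte-identical file.
#'
#' @param results a `"wflm"` object or list of them (possibly empty).
#' @param path output path.
#' @param config optional named list echoed into the header.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, config = NULL) {
  df <- if (length(results) == 0L && !inherits(results, "wflm")) {
    data.frame(region_id = character(0), n = integer(0), m = integer(0),
               K_beta_used = integer(0), df1 = integer(0), df2 = integer(0),
               F = numeric(0), P = character(0), weights = character(0),
               basis = character(0))
  } else {
    tb <- results_table(results)
    tb$F <- sprintf("%.10g", tb$F)
    tb$P <- sprintf("%.12e", tb$P)
    tb
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(config))
    writeLines(sprintf("# %s = %s", nm,
                       paste(format(config[[nm]]), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an association results TSV
#'
#' @param path file written by [write_results()].
#' @return data.frame with numeric `F` and `P`.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write simulated fixture files for a region panel
#'
#' Writes, per the panel's first region or all regions, the plain-text
#' formats the reader functions consume: dosage matrix + positions sidecar,
#' a phenotype TSV with a null trait, and (family panels) the relationship
#' matrix with ID header.
#'
#' @param panel a [region_panel()] result.
#' @param prefix output path prefix.
#' @param h2 heritability of the simulated null trait.
#' @return Named character vector of the files written, invisibly.
#' @export
write_panel_fixtures <- function(panel, prefix, h2 = 0.29) {
  files <- c()
  for (r in seq_along(panel$regions)) {
    reg <- panel$regions[[r]]
    gp <- sprintf("%s_region%02d_dosages.txt", prefix, r)
    pp <- sprintf("%s_region%02d_positions.txt", prefix, r)
    utils::write.table(cbind(reg$ids, reg$G), gp, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(chrom = "chr1", pos = reg$positions), pp,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, genotypes = gp, positions = pp)
  }
  y <- simulate_trait(panel$regions[[1L]], beta = NULL, h2 = h2, R = panel$R)
  ph <- paste0(prefix, "_pheno.tsv")
  utils::write.table(data.frame(id = panel$regions[[1L]]$ids,
                                trait = sprintf("%.10g", y)),
                     ph, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, phenotypes = ph)
  if (!is.null(panel$R)) {
    kp <- paste0(prefix, "_kinship.txt")
    write_kinship(panel$R, kp)
    files <- c(files, kinship = kp)
  }
  invisible(files)
}
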
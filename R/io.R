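# Readers, writers and the orchestrated pipeline.
#
# TSV (UTF-8, '.' decimal) is the canonical tabular dialect; configuration,
# grid geometry and the run manifest are JSON.

#' Read an expression matrix TSV
#'
#' Expects a header row of sample ids, gene ids in the first column and a
#' numeric body.  Duplicate gene ids, missing and non-numeric cells are
#' rejected with coordinates.
#'
#' @param path Matrix TSV path.
#' @param annotation Optional sample-annotation TSV path with columns
#'   `sample`, `condition` and covariates; required to build a full
#'   [expression_dataset()].
#' @param scale `"log2"` or `"intensity"`.
#' @return An `ExpressionDataset` (or a bare matrix when `annotation` is
#'   `NULL`).
#' @export
read_expression_tsv <- function(path, annotation = NULL, scale = "log2") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("expected gene-id column plus >= 1 sample column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stopf("duplicate gene id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stopf("non-numeric cell at gene '%s', sample '%s'", ids[bad], names(body)[j])
    }
    if (anyNA(v)) {
      stopf("missing value at gene '%s', sample '%s'",
            ids[which(is.na(v))[1]], names(body)[j])
    }
  }
  x <- as.matrix(body)
  rownames(x) <- ids
  if (is.null(annotation)) return(x)
  ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  if (is.null(ann$sample) || is.null(ann$condition)) {
    stopf("annotation needs `sample` and `condition` columns")
  }
  m <- match(colnames(x), ann$sample)
  if (anyNA(m)) stopf("samples missing from annotation: %s",
                      paste(colnames(x)[is.na(m)], collapse = ", "))
  samples <- ann[m, setdiff(names(ann), "sample"), drop = FALSE]
  rownames(samples) <- colnames(x)
  expression_dataset(x, samples, scale = scale)
}

#' Write an expression matrix (or dataset) as TSV
#'
#' @param x Matrix or `ExpressionDataset`.
#' @param path Output path.
#' @param annotation_path Optional path for the sample-annotation TSV.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, annotation_path = NULL) {
  if (inherits(x, "ExpressionDataset")) {
    if (!is.null(annotation_path)) {
      ann <- cbind(sample = rownames(x$samples), x$samples)
      utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    x <- x$exprs
  }
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members.  Duplicate members within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warnf("empty gene-set file: %s", path)
    return(structure(list(), description = character(0)))
  }
  sets <- list()
  desc <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("GMT line has fewer than 3 fields: %s", substr(ln, 1, 40))
    if (!nzchar(f[1])) stopf("blank set name in GMT")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) < 1L) stopf("set '%s' has no members", f[1])
    if (anyDuplicated(members)) {
      warnf("set '%s': removed %d duplicate member(s)", f[1],
            sum(duplicated(members)))
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  structure(sets, description = desc)
}

#' Write a gene-set library as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge list (TSV or SIF)
#'
#' TSV needs `source` and `target` columns (optional `interaction`,
#' `source_type`, `target_type`).  SIF lines are
#' `source interaction target [target2 ...]`.
#'
#' @param path File path.
#' @param format `"tsv"` or `"sif"` (guessed from the extension by
#'   default).
#' @return Data frame with `source`, `target` and any extra columns.
#' @export
read_edge_list <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(ln) {
      f <- strsplit(trimws(ln), "[\t ]+")[[1]]
      if (length(f) < 3L) stopf("SIF line needs >= 3 fields: %s", ln)
      data.frame(source = f[1], target = f[-(1:2)], interaction = f[2],
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(df$source) || is.null(df$target)) {
    stopf("edge TSV needs `source` and `target` columns")
  }
  df
}

#' Read / write a grid layout as JSON
#' @param path JSON path.
#' @return `read_layout_json`: a [grid_layout()].
#' @export
read_layout_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_layout(rows = j$rows, cols = j$cols, pitch = j$pitch %||% 18,
              spot_radius = j$spot_radius %||% 3,
              marker_radius = j$marker_radius %||% (2 * (j$spot_radius %||% 3)),
              margin = j$margin %||% (2 * (j$marker_radius %||% (2 * (j$spot_radius %||% 3))) + 2))
}

#' @rdname read_layout_json
#' @param layout A [grid_layout()].
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(layout[c("rows", "cols", "pitch", "spot_radius",
                                "marker_radius", "margin")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the orchestrated analysis pipeline
#'
#' Executes, on a synthetic dataset (or user-supplied TSV files), the
#' stages: simulate/load -> preprocess -> differential expression ->
#' differential co-expression -> network/ORA (when an edge list is given)
#' -> clinical statistics, writing every stage's table under `out_dir`
#' together with a JSON run manifest (config snapshot, package version,
#' per-stage row counts and output MD5 checksums).  Reruns with the same
#' configuration are byte-identical.
#'
#' @param config Nested list; see the package vignette.  Recognized
#'   sections: `simulate` (arguments of [sim_config()]), or `input`
#'   (`matrix`, `annotation`, `scale`), `preprocess`, `de` (covariates),
#'   `coexpress`, `network` (`edges`, `gmt`, `literature`), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("dcx")),
                   stages = list())
  t0 <- Sys.time()
  note <- function(stage, files, counts) {
    manifest$stages[[stage]] <<- list(
      outputs = files,
      md5 = as.list(tools::md5sum(files)),
      counts = counts)
    message(sprintf("[%s] done (%s)", stage,
                    paste(basename(files), collapse = ", ")))
  }
  fp <- function(...) file.path(out_dir, ...)

  # --- input -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    mods <- lapply(sim_args$modules %||% list(), function(m) {
      do.call(module_spec, m)
    })
    sim_args$modules <- mods
    sim_args$seed <- sim_args$seed %||% seed
    sim <- simulate_expression(do.call(sim_config, sim_args))
    dataset <- sim$dataset
    f <- c(fp("expression.tsv"), fp("samples.tsv"))
    write_expression_tsv(dataset, f[1], f[2])
    note("input", f, list(genes = nrow(dataset$exprs), samples = ncol(dataset$exprs)))
  } else if (!is.null(config$input)) {
    if (!file.exists(config$input$matrix)) {
      stopf("input stage: matrix file not found: %s", config$input$matrix)
    }
    dataset <- read_expression_tsv(config$input$matrix, config$input$annotation,
                                   scale = config$input$scale %||% "log2")
    note("input", config$input$matrix,
         list(genes = nrow(dataset$exprs), samples = ncol(dataset$exprs)))
  } else stopf("config needs a `simulate` or `input` section")

  # --- preprocess ------------------------------------------------------
  pp_cfg <- do.call(preproc_config, config$preprocess %||% list())
  pp <- preprocess_matrix(dataset, pp_cfg)
  f <- c(fp("preprocessed.tsv"), fp("cv_filter_report.tsv"))
  write_expression_tsv(pp$dataset, f[1])
  utils::write.table(pp$report, f[2], sep = "\t", quote = FALSE, row.names = FALSE)
  note("preprocess", f, list(genes_kept = nrow(pp$dataset$exprs)))

  # --- differential expression ----------------------------------------
  de <- fit_gene_ancova(pp$dataset, covariates = config$de$covariates %||% character())
  f <- fp("diffexpr.tsv")
  utils::write.table(de, f, sep = "\t", quote = FALSE, row.names = FALSE)
  note("diffexpr", f, list(genes = nrow(de),
                           significant = sum(de$p_adj < 0.05)))

  # --- differential co-expression -------------------------------------
  cx_args <- config$coexpress %||% list()
  cx_args$seed <- cx_args$seed %||% seed
  cx <- differential_coexpression(pp$dataset, do.call(coex_params, cx_args))
  f <- fp("coexpress_groups.tsv")
  utils::write.table(cx$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
  note("coexpress", f, list(groups = nrow(cx$table), dcg = sum(cx$table$is_dcg)))

  # --- network ---------------------------------------------------------
  if (!is.null(config$network$edges)) {
    if (!file.exists(config$network$edges)) {
      stopf("network stage: edge list not found: %s", config$network$edges)
    }
    g <- build_graph(read_edge_list(config$network$edges))
    cent <- betweenness_table(g)
    atk <- topological_attack(g, "betweenness", recompute = TRUE)
    files <- c(fp("centrality.tsv"), fp("attack_curve.tsv"))
    utils::write.table(cent, files[1], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(atk, files[2], sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- list(nodes = igraph::vcount(g), edges = igraph::ecount(g))
    if (!is.null(config$network$gmt)) {
      lib <- read_gmt(config$network$gmt)
      dcg_genes <- unique(unlist(cx$groups[cx$table$is_dcg]))
      if (length(dcg_genes) > 0) {
        ora <- ora_enrichment(dcg_genes, lib, universe = rownames(pp$dataset$exprs))
        files <- c(files, fp("ora.tsv"))
        utils::write.table(ora, files[3], sep = "\t", quote = FALSE, row.names = FALSE)
        counts$ora_sets <- nrow(ora)
      }
    }
    note("network", files, counts)
  }

  # --- clinical statistics --------------------------------------------
  clin <- if (!is.null(config$clinical$table)) {
    utils::read.delim(config$clinical$table, stringsAsFactors = FALSE)
  } else {
    simulate_clinical_table(n_per_group = ncol(dataset$exprs) / 2, seed = seed)
  }
  ct <- clinical_comparison_table(
    clin,
    continuous = intersect(c("age", "bmi", "bal_eos_pct", "blood_eos", "il5", "rbm_um"),
                           names(clin)),
    categorical = intersect(c("sex", "oral_steroid"), names(clin)))
  f <- fp("clinical_stats.tsv")
  utils::write.table(ct, f, sep = "\t", quote = FALSE, row.names = FALSE)
  note("clinical_stats", f, list(variables = nrow(ct)))

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
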
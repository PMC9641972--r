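#' Assemble a pipeline configuration
#'
#' All thresholds default to the conventional values used throughout the
#' package: `|r| > 0.7` and FDR `q < 0.01` for network edges, `|betaNTI|`
#' threshold 2 and `|RC_bray|` threshold 0.95 for the process
#' classification, 999 randomizations/permutations, top 500 taxa for the
#' network. Every default can be overridden, from R or from a YAML file.
#'
#' @param seed integer seed governing every stochastic stage.
#' @param input optional list of paths (`table`, `tree`, `meta`); when
#'   absent, the synthetic study layout is generated.
#' @param stages subset of
#'   `c("diversity", "niche", "assembly", "ncm", "network", "mantel")`.
#' @param n_null,n_perm randomizations for null models / permutation tests.
#' @param r_threshold,q_threshold,bnti_threshold,rc_threshold,top_k
#'   analysis constants (see description).
#' @param n_taxa,N synthetic layout size (used only when simulating).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, input = NULL,
                            stages = c("diversity", "niche", "assembly",
                                       "ncm", "network", "mantel"),
                            n_null = 999, n_perm = 999,
                            r_threshold = 0.7, q_threshold = 0.01,
                            bnti_threshold = 2, rc_threshold = 0.95,
                            top_k = 500, n_taxa = 400, N = 5000) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = seed, input = input, stages = stages,
                 n_null = n_null, n_perm = n_perm,
                 r_threshold = r_threshold, q_threshold = q_threshold,
                 bnti_threshold = bnti_threshold,
                 rc_threshold = rc_threshold, top_k = top_k,
                 n_taxa = n_taxa, N = N),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

group_means <- function(values, groups) {
  out <- tapply(values, groups, mean)
  as.list(round(unclass(out), 6))
}

#' Run the full analysis pipeline
#'
#' Executes (subsets of) the stages in dependency order on either supplied
#' input files or the synthetic 75-sample study layout, and returns a
#' machine-readable report. Identical configurations (including the seed)
#' produce byte-identical report files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, the report JSON
#'   and per-stage tables are written there.
#' @return the report, a named list (invisibly written to
#'   `out_dir/report.json` when requested).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_active <- function(s) s %in% config$stages

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_msg("stage %-10s done in %.1f s", name,
            proc.time()[["elapsed"]] - t0)
    res
  }

  # --- data -----------------------------------------------------------
  data <- run_stage("input", {
    if (is.null(config$input)) {
      generate_study_layout(seed = config$seed, n_taxa = config$n_taxa,
                            N = config$N)
    } else {
      for (what in c("table", "meta"))
        if (is.null(config$input[[what]]))
          stop(sprintf("missing input '%s'", what))
      tab <- read_otu_table(config$input$table)
      tree <- if (!is.null(config$input$tree))
        read_newick(config$input$tree) else NULL
      meta <- read_sample_metadata(config$input$meta)
      list(table = tab, tree = tree, meta = meta)
    }
  })
  if (stage_active("assembly") && is.null(data$tree))
    stop("stage 'assembly' needs a phylogeny: missing input 'tree'")
  aligned <- align_community(data$table, tree = data$tree, meta = data$meta)
  table <- aligned$table
  meta <- aligned$meta
  groups <- meta$group

  report <- list(seed = config$seed,
                 n_samples = ncol(table), n_taxa = nrow(table),
                 groups = as.list(table(groups)),
                 thresholds = list(r = config$r_threshold,
                                   q = config$q_threshold,
                                   bnti = config$bnti_threshold,
                                   rc = config$rc_threshold,
                                   n_null = config$n_null,
                                   n_perm = config$n_perm))
  outputs <- list()

  if (stage_active("diversity")) {
    report$diversity <- run_stage("diversity", {
      alpha <- alpha_indices(table)
      outputs$alpha <- alpha
      bc <- bray_curtis(table)
      disp <- beta_dispersion(bc, groups)
      list(
        alpha_group_means = lapply(
          c(observed = "observed", chao1 = "chao1", ace = "ace",
            shannon = "shannon"),
          function(col) group_means(alpha[[col]], groups)),
        kruskal_shannon = kruskal_wallis(alpha$shannon, groups),
        permanova = unclass(permanova(bc, groups, n_perm = config$n_perm,
                                      seed = config$seed)),
        anosim = unclass(anosim_test(bc, groups, n_perm = config$n_perm,
                                     seed = config$seed + 1L)),
        beta_dispersion_means = lapply(disp, function(v) round(mean(v), 6)))
    })
  }

  if (stage_active("niche")) {
    report$niche <- run_stage("niche", {
      cb <- community_breadth(table)
      list(community_breadth_group_means = group_means(cb, groups),
           kruskal = kruskal_wallis(cb, groups))
    })
  }

  if (stage_active("assembly")) {
    report$assembly <- run_stage("assembly", {
      res <- assembly_processes(table, aligned$tree, groups,
                                n_null = config$n_null,
                                bnti_threshold = config$bnti_threshold,
                                rc_threshold = config$rc_threshold,
                                seed = config$seed + 2L)
      outputs$assembly_pairs <- res$pairs
      parts <- res$partition
      setNames(lapply(seq_len(nrow(parts)), function(i)
        lapply(as.list(parts[i, -1]), round, 6)), parts$group)
    })
  }

  if (stage_active("ncm")) {
    report$ncm <- run_stage("ncm", {
      fits <- lapply(split(seq_along(groups), groups), function(idx) {
        fit <- ncm_fit(otu_table(otu_counts(table)[, idx, drop = FALSE]))
        list(m = round(fit$m, 6), Nm = round(fit$Nm, 4),
             r_squared = round(fit$r_squared, 6))
      })
      fits
    })
  }

  if (stage_active("network")) {
    report$network <- run_stage("network", {
      top <- select_top_taxa(table, k = config$top_k)
      net <- suppressWarnings(
        spearman_edges(top, r_threshold = config$r_threshold,
                       q_threshold = config$q_threshold))
      outputs$network_edges <- igraph::as_data_frame(net, what = "edges")
      outputs$node_topology <- if (igraph::vcount(net) >= 2)
        node_topology(net) else NULL
      topo <- network_topology(net, seed = config$seed + 3L)
      subs <- lapply(split(meta$sample_id, groups), function(ids) {
        sub <- extract_subnetwork(net, top, ids)
        list(n_nodes = igraph::vcount(sub), n_edges = igraph::ecount(sub),
             graph_density = round(igraph::edge_density(sub), 6))
      })
      list(meta_network = lapply(topo, function(v)
        if (is.numeric(v)) round(v, 6) else v),
        subnetworks = subs)
    })
  }

  if (stage_active("mantel")) {
    report$mantel <- run_stage("mantel", {
      res <- list()
      for (g in unique(groups)) {
        sub_meta <- meta[groups == g, , drop = FALSE]
        vars <- env_variables(sub_meta)
        vars <- vars[vapply(sub_meta[vars],
                            function(v) !anyNA(v) && sd(v) > 0, logical(1))]
        if (length(vars) == 0) next
        sub_tab <- otu_table(
          otu_counts(table)[, sub_meta$sample_id, drop = FALSE])
        bc <- bray_curtis(sub_tab)
        ed <- env_distance(sub_meta, vars)
        geo <- haversine_matrix(sub_meta$latitude, sub_meta$longitude,
                                ids = sub_meta$sample_id)
        fit <- partial_mantel_test(bc, ed, geo, n_perm = config$n_perm,
                                   seed = config$seed + 4L,
                                   controlled = "geographic")
        res[[g]] <- list(r = round(fit$r, 6), p_value = fit$p_value,
                         variables = vars)
      }
      res
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null")
    for (nm in names(outputs)) {
      if (is.null(outputs[[nm]])) next
      write.table(outputs[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' Check a pipeline report against the published schema
#'
#' Verifies that every stage object present in the report carries the
#' fields required by `inst/extdata/report_schema.json`.
#'
#' @param report a report list from [run_pipeline()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "report_schema.json",
                                            package = "assemblyscope"))
  for (key in unlist(schema$required))
    if (is.null(report[[key]]))
      stop(sprintf("report is missing required field '%s'", key))
  for (stage in names(schema$stages)) {
    if (is.null(report[[stage]])) next
    for (field in unlist(schema$stages[[stage]]$required)) {
      ok <- !is.null(report[[stage]][[field]]) ||
        all(vapply(report[[stage]],
                   function(el) !is.null(el[[field]]), logical(1)))
      if (!ok)
        stop(sprintf("stage '%s' is missing required field '%s'",
                     stage, field))
    }
  }
  invisible(TRUE)
}
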
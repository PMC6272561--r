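#' @title Study orchestration
#' @name cooperativity_pipeline
#' @description
#' Runs the full analysis for one or two study arms (e.g. normal vs
#' cooperative binding): RMSD, ring perception and pi-pi stacking,
#' close-contact fractions, hydrogen bonds, MM-PB/SA / MM-GB/SA
#' breakdowns, per-residue decomposition, and the cross-arm ddG
#' permutation comparison. Deterministic given config + seed; the JSON
#' report carries a provenance block (config hash, seed, package version)
#' and no timestamps, so identical inputs give byte-identical reports.
NULL

#' Analysis configuration
#'
#' @param arms list of arms, each `list(name =, ensemble = <pdb path>,
#'   topology = <sidecar path>)`.
#' @param ligand_partition ligand of interest (default "ligand1").
#' @param include_second_ligand treat a second ligand copy as receptor
#'   when scoring the first (default TRUE).
#' @param solvent_models subset of c("GB", "PB").
#' @param stacking_cutoff,contact_cutoff Angstrom (defaults 7 and 5).
#' @param hbond_distance,hbond_angle H-bond criteria (3.5 Angstrom,
#'   120 deg).
#' @param parallel_max,perpendicular_min stacking class thresholds, deg.
#' @param n_resamples,seed permutation-test settings.
#' @param energy_frames optional frame subset for the (costly) energy
#'   stages; NULL = all frames.
#' @param solvent a [solvent_params()] object.
#' @param output_dir where `run_analysis` writes the report files.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(arms,
                            ligand_partition = "ligand1",
                            include_second_ligand = TRUE,
                            solvent_models = "GB",
                            stacking_cutoff = 7.0,
                            contact_cutoff = 5.0,
                            hbond_distance = 3.5,
                            hbond_angle = 120,
                            parallel_max = 30,
                            perpendicular_min = 60,
                            n_resamples = 999L,
                            seed = 1L,
                            energy_frames = NULL,
                            solvent = solvent_params(),
                            output_dir = NULL) {
  if (length(arms) < 1L) stop("analysis_config: at least one arm")
  stopifnot(stacking_cutoff > 0, contact_cutoff > 0, hbond_distance > 0,
            all(solvent_models %in% c("GB", "PB")))
  structure(list(arms = arms, ligand_partition = ligand_partition,
                 include_second_ligand = include_second_ligand,
                 solvent_models = solvent_models,
                 stacking_cutoff = stacking_cutoff,
                 contact_cutoff = contact_cutoff,
                 hbond_distance = hbond_distance,
                 hbond_angle = hbond_angle,
                 parallel_max = parallel_max,
                 perpendicular_min = perpendicular_min,
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed),
                 energy_frames = energy_frames,
                 solvent = solvent, output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis config from a JSON file
#'
#' @param path JSON file with the [analysis_config()] fields.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  solvent <- do.call(solvent_params, as.list(doc[["solvent"]] %||% list()))
  args <- doc[setdiff(names(doc), "solvent")]
  args$solvent <- solvent
  do.call(analysis_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed for ", input, ": ",
         conditionMessage(e), call. = FALSE))
}

auto_hbond_partners <- function(top) {
  el <- toupper(trimws(top$atoms$element))
  polar <- which(el %in% c("N", "O"))
  is_h <- el == "H"
  has_h <- vapply(polar, function(d) {
    nb <- c(top$bonds[top$bonds[, 1L] == d, 2L],
            top$bonds[top$bonds[, 2L] == d, 1L])
    any(is_h[nb])
  }, logical(1))
  list(donors = polar[has_h], acceptors = polar)
}

analyze_arm <- function(arm, cfg) {
  top <- if (inherits(arm$topology, "topology")) arm$topology else
    stage("read_topology", arm$topology, read_topology(arm$topology))
  ens <- if (inherits(arm$ensemble, "ensemble")) arm$ensemble else
    stage("read_ensemble", arm$ensemble, read_ensemble(arm$ensemble, top))

  sel <- backbone_selection(top)
  if (!length(sel))
    sel <- which(top$atoms$partition == "receptor" &
                   toupper(top$atoms$element) != "H")
  rmsd <- stage("rmsd", arm$name, backbone_rmsd_series(ens, 1L, sel))

  rings <- stage("rings", arm$name,
                 perceive_rings(top, ens$frames[[1L]]))
  stacking <- stage("stacking", arm$name,
                    detect_stacking(ens, rings, cfg$stacking_cutoff,
                                    parallel_max = cfg$parallel_max,
                                    perpendicular_min =
                                      cfg$perpendicular_min))
  contacts <- stage("contacts", arm$name,
                    close_contact_fraction(ens, cfg$ligand_partition,
                                           cfg$contact_cutoff))
  hb_part <- auto_hbond_partners(top)
  part <- top$atoms$partition
  hb_pairs <- expand.grid(d = hb_part$donors, a = hb_part$acceptors)
  hb_pairs <- hb_pairs[part[hb_pairs$d] != part[hb_pairs$a], ]
  hbonds <- if (nrow(hb_pairs)) {
    stage("hbonds", arm$name,
          hydrogen_bonds(ens, unique(hb_pairs$d), unique(hb_pairs$a),
                         cfg$hbond_distance, cfg$hbond_angle))
  } else data.frame()
  if (NROW(hbonds))
    hbonds <- hbonds[part[hbonds$donor_atom] != part[hbonds$acceptor_atom], ]

  breakdowns <- lapply(cfg$solvent_models, function(model)
    stage(paste0("mm", tolower(model), "sa"), arm$name,
          single_trajectory_mmgbsa(ens, cfg$solvent, model,
                                   cfg$ligand_partition,
                                   cfg$include_second_ligand,
                                   frames = cfg$energy_frames)))
  names(breakdowns) <- cfg$solvent_models
  decomposition <- if ("GB" %in% cfg$solvent_models)
    stage("decomposition", arm$name,
          per_residue_decomposition(ens, cfg$solvent,
                                    cfg$ligand_partition,
                                    cfg$include_second_ligand,
                                    frames = cfg$energy_frames)) else NULL
  list(name = arm$name, ensemble = ens, rmsd = rmsd, rings = rings,
       stacking = stacking, contacts = contacts, hbonds = hbonds,
       breakdowns = breakdowns, decomposition = decomposition)
}

#' Run the full cooperative-binding analysis
#'
#' @param cfg an [analysis_config()] (or a path to its JSON form).
#' @return a `study_report` list: per-arm results, cross-arm comparisons
#'   (when two arms are given), and a provenance block. When
#'   `cfg$output_dir` is set, `report.json` and the TSV tables
#'   (`table1.tsv`, `decomposition.tsv`, `contacts.tsv`, `stacking.tsv`,
#'   `hbonds.tsv`, `rmsd.tsv`) are written there.
#' @export
run_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  stopifnot(inherits(cfg, "analysis_config"))
  arms <- lapply(cfg$arms, analyze_arm, cfg = cfg)
  names(arms) <- vapply(cfg$arms, function(a) a$name, character(1))

  comparisons <- list()
  if (length(arms) >= 2L) {
    ref <- arms[[1L]]
    for (k in seq(2L, length(arms))) {
      for (model in cfg$solvent_models) {
        cmp <- compare_breakdowns(ref$breakdowns[[model]],
                                  arms[[k]]$breakdowns[[model]],
                                  cfg$n_resamples, cfg$seed)
        comparisons[[paste(names(arms)[1L], "vs", names(arms)[k], model,
                           sep = "_")]] <- cmp
      }
    }
  }
  report <- structure(list(arms = arms, comparisons = comparisons,
                           config = cfg,
                           provenance = list(
                             config_hash = config_hash(cfg),
                             seed = cfg$seed,
                             package_version =
                               as.character(utils::packageVersion(
                                 "coopbind")))),
                      class = "study_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

config_hash <- function(cfg) {
  cfg$output_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, unclass_deep) else x
}

# ---- formatters ---------------------------------------------------------

#' Decimal round-half-even string formatting
#'
#' Formats a value to `digits` decimals with round-half-even applied to
#' the decimal representation (12 significant decimals of the stored
#' double), so e.g. -1.005 renders "-1.00" and -38.855 renders "-38.86" -
#' unlike C's `sprintf`, which ties on the binary value.
#'
#' @param x numeric scalar (or vector).
#' @param digits decimal places.
#' @return character.
#' @export
round_half_even_str <- function(x, digits = 2L) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    neg <- v < 0
    s <- sprintf("%.12f", abs(v))
    dot <- regexpr(".", s, fixed = TRUE)
    d <- gsub(".", "", s, fixed = TRUE)       # all digits
    int_len <- dot - 1L
    keep <- int_len + digits
    head_digits <- substr(d, 1L, keep)
    rest <- substr(d, keep + 1L, nchar(d))
    half <- paste0("5", strrep("0", nchar(rest) - 1L))
    bump <- if (rest > half) TRUE
      else if (rest < half) FALSE
      else (as.integer(substr(head_digits, keep, keep)) %% 2L) == 1L
    if (bump) head_digits <- str_increment(head_digits)
    if (nchar(head_digits) > keep) int_len <- int_len + 1L
    int_part <- substr(head_digits, 1L, nchar(head_digits) - digits)
    frac_part <- substr(head_digits, nchar(head_digits) - digits + 1L,
                        nchar(head_digits))
    out <- if (digits > 0L) paste0(int_part, ".", frac_part) else int_part
    if (neg && grepl("[1-9]", out)) out <- paste0("-", out)
    out
  }, character(1))
}

str_increment <- function(s) {
  d <- as.integer(strsplit(s, "")[[1L]])
  i <- length(d)
  repeat {
    d[i] <- d[i] + 1L
    if (d[i] < 10L) break
    d[i] <- 0L
    i <- i - 1L
    if (i == 0L) { d <- c(1L, d); break }
  }
  paste(d, collapse = "")
}

fmt_pm <- function(mean, std)
  paste0(round_half_even_str(mean, 2L), " ± ",
         round_half_even_str(std, 2L))

#' Format an energy breakdown as report table rows
#'
#' Rows ordered as the conventional component table (dE_ele, dE_vdw,
#' dE_gas, dG_nonpolar, dG_sol, dG_ele, dG_bind), values formatted
#' "mean ± std" to 2 decimals under decimal round-half-even.
#'
#' @param b an `energy_breakdown`.
#' @return data.frame with `term`, `mean`, `sample_std`, `formatted`.
#' @export
format_breakdown_table <- function(b) {
  stopifnot(inherits(b, "energy_breakdown"))
  s <- b$summary[match(BREAKDOWN_TERMS, b$summary$term), ]
  s$formatted <- fmt_pm(s$mean, s$sample_std)
  rownames(s) <- NULL
  s[, c("term", "mean", "sample_std", "formatted")]
}

#' Format a contact profile as percentage rows
#'
#' Residues sorted by number; fractions emitted as percentages with one
#' decimal.
#'
#' @param p a `contact_profile`.
#' @return data.frame with `resnum`, `resname`, `percent` (numeric) and
#'   `formatted` (character, e.g. "70.0").
#' @export
format_contact_figure_data <- function(p) {
  stopifnot(inherits(p, "contact_profile"))
  out <- as.data.frame(p)[order(p$resnum), ]
  out$percent <- out$contact_fraction * 100
  out$formatted <- sprintf("%.1f", out$percent)
  rownames(out) <- NULL
  out[, c("resnum", "resname", "percent", "formatted")]
}

# ---- report writing -----------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bind_arm <- function(f) {
    do.call(rbind, lapply(report$arms, function(a) {
      df <- f(a)
      if (is.null(df) || !NROW(df)) return(NULL)
      cbind(arm = a$name, df, stringsAsFactors = FALSE)
    }))
  }
  t1 <- bind_arm(function(a)
    do.call(rbind, lapply(names(a$breakdowns), function(m)
      cbind(model = m, format_breakdown_table(a$breakdowns[[m]]),
            stringsAsFactors = FALSE))))
  write_tsv(t1, file.path(out_dir, "table1.tsv"))
  dec <- bind_arm(function(a) {
    if (is.null(a$decomposition)) return(NULL)
    d <- as.data.frame(a$decomposition)
    d$formatted <- fmt_pm(d$mean, d$sample_std)
    d
  })
  if (!is.null(dec)) write_tsv(dec, file.path(out_dir,
                                              "decomposition.tsv"))
  write_tsv(bind_arm(function(a) format_contact_figure_data(a$contacts)),
            file.path(out_dir, "contacts.tsv"))
  stk <- bind_arm(function(a) a$stacking$summaries)
  if (!is.null(stk)) write_tsv(stk, file.path(out_dir, "stacking.tsv"))
  hb <- bind_arm(function(a) a$hbonds)
  if (!is.null(hb)) write_tsv(hb, file.path(out_dir, "hbonds.tsv"))
  write_tsv(bind_arm(function(a)
    data.frame(frame = seq_along(a$rmsd$rmsd), rmsd = a$rmsd$rmsd)),
    file.path(out_dir, "rmsd.tsv"))

  json <- list(
    provenance = report$provenance,
    arms = lapply(report$arms, function(a) list(
      n_frames = n_frames(a$ensemble),
      rmsd = list(mean = a$rmsd$summary$mean,
                  sample_std = a$rmsd$summary$sample_std,
                  n_frames = a$rmsd$summary$n_frames),
      breakdowns = lapply(a$breakdowns, function(b)
        list(solvent_model = b$solvent_model, summary = b$summary,
             protocol = b$protocol)),
      decomposition = if (!is.null(a$decomposition))
        as.data.frame(a$decomposition) else NULL,
      contacts = format_contact_figure_data(a$contacts),
      stacking = a$stacking$summaries,
      hbonds = a$hbonds)),
    comparisons = report$comparisons)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

# ---- command-line interface --------------------------------------------

#' Command-line entry point
#'
#' `coopbind analyze --config <file>` runs [run_analysis()];
#' `coopbind synth --spec <file> --out <dir>` writes a synthetic arm
#' (`complex.pdb`, `topology.json`, `manifest.json`) from a JSON
#' [synthetic_spec()].
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return invisibly, the result of the subcommand.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: coopbind analyze --config <file> [--out <dir>]",
                 "       coopbind synth --spec <file> --out <dir>",
                 sep = "\n")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1L]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--") || i + 1L > length(args))
      stop(usage, call. = FALSE)
    opts[[substring(args[i], 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  if (cmd == "analyze") {
    if (is.null(opts$config)) stop(usage, call. = FALSE)
    cfg <- read_analysis_config(opts$config)
    if (!is.null(opts$out)) cfg$output_dir <- opts$out
    invisible(run_analysis(cfg))
  } else if (cmd == "synth") {
    if (is.null(opts$spec) || is.null(opts$out)) stop(usage, call. = FALSE)
    doc <- jsonlite::fromJSON(opts$spec, simplifyDataFrame = FALSE)
    spec <- do.call(synthetic_spec, doc)
    invisible(write_synthetic_arm(spec, opts$out))
  } else stop(usage, call. = FALSE)
}
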
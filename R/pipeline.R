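#' Known input CSV schemas
#'
#' Column contracts for the long-format CSV tables the pipeline reads.
#'
#' @return named list: schema name -> character vector of required columns.
#' @export
input_schemas <- function() {
  list(
    quantitation = c("sample_type", "level", "run_id", "nominal_ng_ml",
                     "analyte_area", "is_area"),
    microsomal = c("species", "time_min", "ratio", "nadph"),
    dialysis = c("matrix", "donor", "receiver"),
    transwell = c("assay", "time_s", "chamber", "conc"),
    nca = c("subject_id", "route", "dose_mg_per_kg", "time_h",
            "conc_ng_per_ml"),
    tissue = c("tissue", "time_h", "content_ng_per_g")
  )
}

#' Validate a CSV file or data.frame against a named schema
#'
#' Checks required columns, then schema-specific row-level rules:
#' concentrations and areas must be non-negative, and per-subject (or
#' per-species) sampling times must be strictly increasing. Violations are
#' reported with the offending column or row index.
#'
#' @param x path to a CSV file, or a data.frame.
#' @param schema_name one of `names(input_schemas())`.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validate_schema <- function(x, schema_name) {
  schemas <- input_schemas()
  if (!schema_name %in% names(schemas)) {
    stop("unknown schema: ", schema_name)
  }
  df <- if (is.character(x)) utils::read.csv(x) else x
  required <- schemas[[schema_name]]
  violations <- character()
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    violations <- c(violations,
                    paste0("missing column: ", missing))
    return(list(ok = FALSE, violations = violations))
  }
  check_nonneg <- function(col) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) paste0("negative ", col, " at row ", bad) else character()
  }
  check_increasing <- function(time_col, by_cols) {
    key <- if (length(by_cols)) {
      interaction(df[by_cols], drop = TRUE)
    } else {
      factor(rep(1, nrow(df)))
    }
    out <- character()
    for (g in split(seq_len(nrow(df)), key)) {
      tt <- df[[time_col]][g]
      bad <- which(diff(tt) <= 0)
      if (length(bad)) {
        out <- c(out, paste0("non-increasing ", time_col, " at row ",
                             g[bad + 1]))
      }
    }
    out
  }
  violations <- c(
    violations,
    switch(schema_name,
      quantitation = c(check_nonneg("analyte_area"), check_nonneg("is_area"),
                       check_nonneg("nominal_ng_ml")),
      microsomal = c(check_nonneg("ratio"),
                     check_increasing("time_min", c("species", "nadph"))),
      dialysis = c(check_nonneg("donor"), check_nonneg("receiver")),
      transwell = c(check_nonneg("conc"),
                    check_increasing("time_s", c("assay", "chamber"))),
      nca = c(check_nonneg("conc_ng_per_ml"),
              check_increasing("time_h", "subject_id")),
      tissue = check_nonneg("content_ng_per_g")
    )
  )
  list(ok = length(violations) == 0, violations = violations)
}

#' Assemble a pipeline run configuration
#'
#' Bundles input paths, assay constants and reporting options. The
#' configuration round-trips losslessly through JSON
#' ([jsonlite::write_json()] / [jsonlite::read_json()]).
#'
#' @param inputs named list of CSV paths, names among
#'   `names(input_schemas())`; stages without inputs are skipped.
#' @param logp compound logP.
#' @param fu_plasma,fu_brain fractions unbound.
#' @param molar_mass g/mol.
#' @param ic50_um in vitro IC50, uM.
#' @param q_ml_min_kg hepatic blood flow for IVIVE, mL/min/kg.
#' @param q_blood_l_h_kg hepatic blood flow for the clearance ratio, L/h/kg.
#' @param lloq assay LLOQ, ng/mL.
#' @param rounding reporting policy, `"none"` or `"table"`.
#' @param seed integer seed echoed into the report.
#' @param out_dir optional output directory for the JSON/text report.
#' @return list of class `run_config`.
#' @export
run_config <- function(inputs = list(), logp = 2.3, fu_plasma = 0.025,
                       fu_brain = 0.057, molar_mass = 483, ic50_um = 1.7,
                       q_ml_min_kg = 90, q_blood_l_h_kg = 3.6, lloq = 0.2,
                       rounding = c("none", "table"), seed = 1L,
                       out_dir = NULL) {
  rounding <- match.arg(rounding)
  bad <- setdiff(names(inputs), names(input_schemas()))
  if (length(bad)) stop("unknown input sections: ", paste(bad, collapse = ", "))
  for (p in unlist(inputs)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  structure(
    list(inputs = inputs, logp = logp, fu_plasma = fu_plasma,
         fu_brain = fu_brain, molar_mass = molar_mass, ic50_um = ic50_um,
         q_ml_min_kg = q_ml_min_kg, q_blood_l_h_kg = q_blood_l_h_kg,
         lloq = lloq, rounding = rounding, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order and for whichever inputs are present: calibration +
#' batch acceptance, the microsomal IVIVE chain, dialysis binding,
#' PAMPA/Caco-2 permeability, per-subject and group NCA (with
#' bioavailability when both routes are present), and tissue/brain
#' disposition. Output depends only on the inputs and configuration; every
#' section records the operation and parameters that produced it in a
#' provenance log.
#'
#' @param config a [run_config()].
#' @return list of class `study_report`: `sections` (named list),
#'   `provenance` (data.frame of section/operation/parameters), `config`.
#'   When `config$out_dir` is set, `report.json` and `report.txt` are
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sections <- list()
  prov <- list()
  note <- function(section, operation, params) {
    prov[[length(prov) + 1]] <<- data.frame(
      section = section, operation = operation,
      params = paste(names(params), unlist(params), sep = "=",
                     collapse = "; "))
  }
  read_in <- function(name) {
    chk <- validate_schema(config$inputs[[name]], name)
    if (!chk$ok) {
      stop("schema violations in ", name, " input:\n  ",
           paste(chk$violations, collapse = "\n  "))
    }
    utils::read.csv(config$inputs[[name]])
  }

  if (!is.null(config$inputs$quantitation)) {
    df <- read_in("quantitation")
    std <- df[df$sample_type == "standard", ]
    fit <- fit_calibration(data.frame(
      nominal = std$nominal_ng_ml, analyte_area = std$analyte_area,
      is_area = std$is_area))
    qc <- df[df$sample_type == "qc", ]
    bc <- back_calculate(fit, qc$analyte_area / qc$is_area)
    qc_tab <- data.frame(level = qc$level, nominal = qc$nominal_ng_ml,
                         run_id = qc$run_id, value = bc$conc)
    sections$quantitation <- list(
      calibration = list(slope = fit$slope, intercept = fit$intercept,
                         r_squared = fit$r_squared,
                         range = unname(fit$range)),
      intra_day = accuracy_precision(qc_tab, "intra_day"),
      inter_day = accuracy_precision(qc_tab, "inter_day")
    )
    note("quantitation", "fit_calibration + accuracy_precision",
         list(weighting = fit$weighting))
  }

  if (!is.null(config$inputs$microsomal)) {
    df <- read_in("microsomal")
    act <- df[df$nadph %in% c(TRUE, "TRUE", "true", 1), ]
    per_species <- lapply(split(act, act$species), function(g) {
      scl <- species_scaling(g$species[1],
                             fu_plasma = config$fu_plasma)
      res <- ivive_chain(
        t_half = fit_monoexponential_decay(g$time_min, g$ratio)$t_half,
        scaling = scl, logp = config$logp)
      unclass(res)
    })
    sections$ivive <- per_species
    note("ivive", "fit_monoexponential_decay + ivive_chain",
         list(logp = config$logp, fu_plasma = config$fu_plasma,
              q = config$q_ml_min_kg))
  }

  if (!is.null(config$inputs$dialysis)) {
    df <- read_in("dialysis")
    sections$binding <- lapply(split(df, df$matrix), function(g) {
      list(percent_bound = mean(percent_bound(g$donor, g$receiver)),
           fu = mean(dialysis_fu(g$donor, g$receiver)))
    })
    note("binding", "percent_bound", list(n = nrow(df)))
  }

  if (!is.null(config$inputs$transwell)) {
    df <- read_in("transwell")
    perm <- list()
    pa <- df[df$assay == "pampa", ]
    if (nrow(pa)) {
      don <- pa[pa$chamber == "donor", ]
      acc <- pa[pa$chamber == "acceptor", ]
      perm$pampa <- pampa_papp(cd_t = don$conc[which.max(don$time_s)],
                               ca_t = acc$conc[which.max(acc$time_s)],
                               t = max(acc$time_s))
    }
    ca <- df[df$assay == "caco2", ]
    if (nrow(ca)) {
      acc <- ca[ca$chamber == "acceptor", ]
      don0 <- ca[ca$chamber == "donor" & ca$time_s == min(ca$time_s), ]
      perm$caco2 <- caco2_papp(acc$time_s, acc$conc,
                               c0 = mean(don0$conc))$papp
    }
    sections$permeability <- perm
    note("permeability", "pampa_papp + caco2_papp", list())
  }

  if (!is.null(config$inputs$nca)) {
    df <- read_in("nca")
    results <- lapply(split(df, df$subject_id), function(g) {
      g <- g[order(g$time_h), ]
      nca(pk_profile(g$time_h, g$conc_ng_per_ml, g$dose_mg_per_kg[1],
                     g$route[1], subject_id = g$subject_id[1],
                     lloq = config$lloq))
    })
    routes <- vapply(results, function(r) r$route, character(1))
    nca_section <- list(
      subjects = lapply(results, unclass),
      groups = lapply(split(results, routes), summarize_nca)
    )
    if (all(c("IV", "PO") %in% routes)) {
      mean_auc <- function(rt) {
        mean(vapply(results[routes == rt], function(r) r$auc_inf, numeric(1)),
             na.rm = TRUE)
      }
      dose_of <- function(rt) results[routes == rt][[1]]$dose
      f_pct <- bioavailability(mean_auc("PO"), mean_auc("IV"),
                               dose_po = dose_of("PO"),
                               dose_iv = dose_of("IV"))
      cl_iv <- mean(vapply(results[routes == "IV"], function(r) r$cl,
                           numeric(1)), na.rm = TRUE)
      nca_section$bioavailability_pct <- f_pct
      nca_section$pct_hepatic_flow <- fraction_of_hepatic_flow(
        cl_iv, config$q_blood_l_h_kg)
    }
    sections$nca <- nca_section
    note("nca", "nca + summarize_nca + bioavailability",
         list(lloq = config$lloq))
  }

  if (!is.null(config$inputs$tissue) && !is.null(sections$nca)) {
    df <- read_in("tissue")
    # matched plasma concentrations: interpolate the PO group mean profile
    po_raw <- utils::read.csv(config$inputs$nca)
    po_raw <- po_raw[po_raw$route == "PO", ]
    plasma_mean <- stats::aggregate(conc_ng_per_ml ~ time_h, po_raw, mean)
    plasma_at <- stats::approx(plasma_mean$time_h, plasma_mean$conc_ng_per_ml,
                               xout = df$time_h, rule = 2)$y
    df$kp <- tissue_kp(df$content_ng_per_g, plasma_at)
    brain <- df[df$tissue == "brain", ]
    dist_section <- list(tissue_kp = df)
    if (nrow(brain)) {
      dist_section$brain <- brain_penetration(
        brain$time_h, brain$content_ng_per_g,
        stats::approx(plasma_mean$time_h, plasma_mean$conc_ng_per_ml,
                      xout = brain$time_h, rule = 2)$y,
        fu_brain = config$fu_brain, fu_plasma = config$fu_plasma,
        ic50 = molar_convert(config$ic50_um, "uM_to_ng_ml",
                             config$molar_mass),
        policy = if (config$rounding == "table") "table" else "none")
    }
    sections$distribution <- dist_section
    note("distribution", "tissue_kp + brain_penetration",
         list(fu_brain = config$fu_brain, fu_plasma = config$fu_plasma))
  }

  sections$constants <- list(
    ic50_ng_ml = molar_convert(config$ic50_um, "uM_to_ng_ml",
                               config$molar_mass),
    molar_mass = config$molar_mass, seed = config$seed
  )

  report <- structure(
    list(sections = sections,
         provenance = do.call(rbind, prov),
         config = config),
    class = "study_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      sections, file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
    txt <- utils::capture.output(print(report))
    writeLines(txt, file.path(config$out_dir, "report.txt"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("DMPK study report\n=================\n")
  for (nm in names(x$sections)) {
    cat("\n[", nm, "]\n", sep = "")
    sec <- x$sections[[nm]]
    if (is.data.frame(sec)) {
      print(sec)
    } else {
      utils::str(sec, max.level = 2, give.attr = FALSE)
    }
  }
  invisible(x)
}
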
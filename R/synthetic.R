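# Synthetic multi-site study generator.
#
# Emulates the situation the tool exists for: several collection sites store
# the same quantity (e.g. age) under different local variable names and
# element ids, tied together only by a shared concept URL, with a known
# linear ground truth relating the response to the covariates.  Every other
# part of the package is testable against these documents without any
# download.

#' Describe one synthetic covariate
#'
#' @param key Site-independent name used in [truth_record()] effects.
#' @param type `"numeric"` or `"categorical"`.
#' @param range Two-element numeric range for numeric covariates (drawn
#'   uniformly).
#' @param levels Character levels for categorical covariates (drawn
#'   uniformly); the first level is the reference carrying effect 0.
#' @param local_name Study-local variable name (defaults to `key`).
#' @param element_id Element identifier token (defaults to `key`).
#' @param concept_url Optional concept URL annotating the element.
#' @return A list of class `nidm_site_var`.
#' @export
site_var <- function(key, type = c("numeric", "categorical"),
                     range = c(0, 1), levels = NULL,
                     local_name = key, element_id = key,
                     concept_url = NULL) {
  type <- match.arg(type)
  if (type == "categorical" && length(levels) < 2L) {
    stop(sprintf("categorical variable '%s' needs at least 2 levels", key),
         call. = FALSE)
  }
  structure(list(key = key, type = type, range = range,
                 levels = as.character(levels), local_name = local_name,
                 element_id = element_id,
                 concept_url = concept_url),
            class = "nidm_site_var")
}

#' Describe one synthetic collection site
#'
#' @param site_id Document label for the site.
#' @param n_subjects Number of subjects (>= 1).
#' @param variables List of [site_var()] covariates; local names must be
#'   unique within the site.
#' @return A list of class `nidm_site_config`.
#' @export
site_config <- function(site_id, n_subjects, variables) {
  stopifnot(n_subjects >= 1L)
  if (inherits(variables, "nidm_site_var")) variables <- list(variables)
  locals <- vapply(variables, function(v) v$local_name, character(1))
  if (anyDuplicated(locals)) {
    stop(sprintf("site '%s': duplicated local variable name(s): %s", site_id,
                 paste(unique(locals[duplicated(locals)]), collapse = ", ")),
         call. = FALSE)
  }
  keys <- vapply(variables, function(v) v$key, character(1))
  structure(list(site_id = site_id, n_subjects = as.integer(n_subjects),
                 variables = stats::setNames(variables, keys)),
            class = "nidm_site_config")
}

#' Define the ground truth of a synthetic study
#'
#' The response is computed as
#' `intercept + sum(effects) + sum(interactions) + Gaussian(0, noise_sd)`.
#' A numeric covariate's effect is `coef * value`. A categorical covariate's
#' effect is a named vector of per-level offsets (levels omitted from the
#' vector, in particular the reference level, contribute 0). An interaction
#' multiplies one numeric covariate's value either by another numeric
#' covariate's value (scalar `coef`) or by a categorical covariate's
#' per-level slope offsets (named `coef` vector).
#'
#' @param intercept Intercept of the true model.
#' @param effects Named list: numeric-covariate key -> scalar slope;
#'   categorical key -> named numeric vector of level offsets.
#' @param interactions List of `list(factors = c(keyA, keyB), coef = ...)`
#'   entries; at most one of the two factors may be categorical.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param dv_element_id,dv_name,dv_label,dv_concept_urls Data element used to
#'   store the response (same across sites, mirroring a derived measure whose
#'   identifier is software-fixed).
#' @return A list of class `nidm_truth`.
#' @export
truth_record <- function(intercept, effects = list(), interactions = list(),
                         noise_sd = 0.5,
                         dv_element_id = "fs_000008", dv_name = "brainvol",
                         dv_label = "supratentorial brain volume",
                         dv_concept_urls = character(0)) {
  stopifnot(noise_sd >= 0)
  structure(list(intercept = intercept, effects = effects,
                 interactions = interactions, noise_sd = noise_sd,
                 dv_element_id = dv_element_id, dv_name = dv_name,
                 dv_label = dv_label, dv_concept_urls = dv_concept_urls),
            class = "nidm_truth")
}

.num_lexical <- function(x) sprintf("%.17g", x)

# per-level offsets for categorical effects: missing levels contribute 0
.level_offset <- function(coef, values) {
  off <- coef[match(as.character(values), names(coef))]
  off[is.na(off)] <- 0
  unname(off)
}

#' Generate one synthetic study document
#'
#' Draws covariates (numeric uniformly over their ranges, categorical
#' uniformly over their levels), computes the response from the ground truth
#' plus Gaussian noise, and packs everything into a [nidm_study()], one
#' observation per (subject, variable). Deterministic given `seed`; the
#' global RNG state is left untouched.
#'
#' @param config A [site_config()].
#' @param truth A [truth_record()]; every key it references must exist in
#'   `config`.
#' @param seed Integer seed.
#' @return A [nidm_study()].
#' @export
generate_study <- function(config, truth, seed) {
  vars <- config$variables
  keys <- names(vars)
  for (k in names(truth$effects)) {
    if (!k %in% keys) {
      stop(sprintf("truth references variable '%s' absent from site '%s'",
                   k, config$site_id), call. = FALSE)
    }
  }
  for (ia in truth$interactions) {
    for (k in ia$factors) {
      if (!k %in% keys) {
        stop(sprintf("truth interaction references variable '%s' absent from site '%s'",
                     k, config$site_id), call. = FALSE)
      }
    }
  }
  n <- config$n_subjects
  values <- with_seed(seed, {
    vals <- lapply(vars, function(v) {
      if (v$type == "numeric") {
        stats::runif(n, v$range[1], v$range[2])
      } else {
        sample(v$levels, n, replace = TRUE)
      }
    })
    noise <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else numeric(n)
    c(vals, list(.noise = noise))
  })
  noise <- values$.noise
  values$.noise <- NULL

  dv <- rep(truth$intercept, n)
  for (k in names(truth$effects)) {
    co <- truth$effects[[k]]
    dv <- dv + if (vars[[k]]$type == "numeric") {
      co * values[[k]]
    } else {
      .level_offset(co, values[[k]])
    }
  }
  for (ia in truth$interactions) {
    a <- ia$factors[1]; b <- ia$factors[2]
    types <- c(vars[[a]]$type, vars[[b]]$type)
    if (all(types == "numeric")) {
      dv <- dv + ia$coef * values[[a]] * values[[b]]
    } else if (sum(types == "categorical") == 1L) {
      num <- if (types[1] == "numeric") a else b
      cat_ <- if (types[1] == "numeric") b else a
      dv <- dv + values[[num]] * .level_offset(ia$coef, values[[cat_]])
    } else {
      stop("interactions between two categorical variables are not supported by the generator",
           call. = FALSE)
    }
  }
  dv <- dv + noise

  elements <- c(
    list(nidm_element(truth$dv_element_id, truth$dv_name, truth$dv_label,
                      concept_urls = truth$dv_concept_urls,
                      value_type = "numeric")),
    lapply(vars, function(v) {
      nidm_element(v$element_id, v$local_name,
                   concept_urls = if (is.null(v$concept_url)) character(0) else v$concept_url,
                   value_type = v$type, levels = v$levels)
    }))
  subjects <- sprintf("sub-%03d", seq_len(n))
  obs_list <- c(
    list(data.frame(subject_id = subjects, element_id = truth$dv_element_id,
                    value = .num_lexical(dv), stringsAsFactors = FALSE)),
    lapply(keys, function(k) {
      v <- vars[[k]]
      data.frame(subject_id = subjects, element_id = v$element_id,
                 value = if (v$type == "numeric") .num_lexical(values[[k]])
                         else as.character(values[[k]]),
                 stringsAsFactors = FALSE)
    }))
  nidm_study(config$site_id, elements, do.call(rbind, obs_list))
}

#' Default two-site study configuration
#'
#' Mirrors the canonical multi-site scenario: a diagnostic group stored under
#' the same local name (`DX_GROUP`) at both sites, a performance-IQ element
#' with a shared identifier token (`PIQ_tca9ck`), and age stored under
#' different local names per site (`age` vs `AGE_yrs`) tied together by the
#' concept URL `http://uri.interlex.org/ilx_0100400`.
#'
#' @param n_per_site Subjects per site (default 50).
#' @return List of two [site_config()]s.
#' @export
default_site_configs <- function(n_per_site = 50L) {
  age_concept <- "http://uri.interlex.org/ilx_0100400"
  list(
    site_config("siteA", n_per_site, list(
      site_var("group", "categorical", levels = c("1", "2"),
               local_name = "DX_GROUP", element_id = "dx_a4f2"),
      site_var("piq", "numeric", range = c(70, 130),
               local_name = "PIQ", element_id = "PIQ_tca9ck"),
      site_var("age", "numeric", range = c(6, 60),
               local_name = "age", element_id = "age_a9k1",
               concept_url = age_concept))),
    site_config("siteB", n_per_site, list(
      site_var("group", "categorical", levels = c("1", "2"),
               local_name = "DX_GROUP", element_id = "dx_b7c3"),
      site_var("piq", "numeric", range = c(70, 130),
               local_name = "PIQ", element_id = "PIQ_tca9ck"),
      site_var("age", "numeric", range = c(6, 60),
               local_name = "AGE_yrs", element_id = "age_b2m8",
               concept_url = age_concept))))
}

#' Default ground truth for the two-site fixture
#'
#' @param noise_sd Gaussian noise standard deviation (default 0.5).
#' @return A [truth_record()] with intercept 1200, age slope 3.5, performance
#'   IQ slope 1.2, and a -25 offset for diagnostic group level `"2"`.
#' @export
default_truth <- function(noise_sd = 0.5) {
  truth_record(intercept = 1200,
               effects = list(age = 3.5, piq = 1.2, group = c("2" = -25)),
               noise_sd = noise_sd)
}

#' Generate a multi-site synthetic study
#'
#' All sites share one ground truth; shared variable keys must agree in type
#' (and, for categorical variables, levels) across sites, and their concept
#' annotations are identical by construction while local names and element
#' ids may differ per site.
#'
#' @param configs List of [site_config()]s; defaults to
#'   [default_site_configs()].
#' @param truth A [truth_record()]; defaults to [default_truth()].
#' @param seed Integer seed; site i uses `seed + i - 1`.
#' @return Named list of [nidm_study()] documents, one per site.
#' @export
generate_multisite <- function(configs = default_site_configs(),
                               truth = default_truth(), seed = 1L) {
  if (inherits(configs, "nidm_site_config")) configs <- list(configs)
  # cross-site consistency of shared keys
  all_keys <- unique(unlist(lapply(configs, function(cf) names(cf$variables))))
  for (k in all_keys) {
    specs <- Filter(Negate(is.null),
                    lapply(configs, function(cf) cf$variables[[k]]))
    types <- unique(vapply(specs, function(v) v$type, character(1)))
    if (length(types) > 1L) {
      stop(sprintf("shared variable '%s' is typed inconsistently across sites (%s)",
                   k, paste(types, collapse = " vs ")), call. = FALSE)
    }
    if (types == "categorical") {
      lv <- specs[[1]]$levels
      for (v in specs[-1]) {
        if (!identical(v$levels, lv)) {
          stop(sprintf("shared categorical variable '%s' has inconsistent levels across sites",
                       k), call. = FALSE)
        }
      }
    }
  }
  docs <- lapply(seq_along(configs), function(i) {
    generate_study(configs[[i]], truth, seed + i - 1L)
  })
  stats::setNames(docs, vapply(configs, function(cf) cf$site_id, character(1)))
}

#' Write a generated multi-site study to disk
#'
#' Serializes each site document as NIDM-lite Turtle and records the ground
#' truth as JSON alongside.
#'
#' @param docs Result of [generate_multisite()].
#' @param truth The [truth_record()] used.
#' @param dir Output directory (created if needed).
#' @return Character vector of the Turtle paths, invisibly.
#' @export
write_multisite <- function(docs, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(docs, function(d) {
    p <- file.path(dir, paste0(d$document_id, ".ttl"))
    write_nidm(d, p)
    p
  }, character(1))
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
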
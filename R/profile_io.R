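.PROFILE_MAGIC <- "ppalign-profile v1"
.DB_MAGIC <- "ppalign-profiledb v1"

.fmt <- function(x) sprintf("%.9g", x)

# serialize one profile to a character vector of lines
profile_lines <- function(profile) {
  p <- profile
  lines <- c(.PROFILE_MAGIC,
             paste("name", p$name),
             paste("length", p$m),
             paste("nseq", p$nseq),
             paste("table_lambda", .fmt(p$table_lambda)),
             paste("lambda_scale", .fmt(p$lambda_scale)),
             paste("provenance", if (is.na(p$provenance)) "NA" else p$provenance))
  for (i in seq_len(p$m)) {
    lines <- c(lines,
               paste("pos", i, p$orig_cols[i]),
               paste(c("f", .fmt(c(p$f[i, ], p$f_gap[i]))), collapse = " "),
               paste(c("t", .fmt(p$t[i, ])), collapse = " "),
               paste(c("s", .fmt(p$s[i, ])), collapse = " "),
               paste("q", .fmt(p$eff[i]), .fmt(p$D[i]), .fmt(p$I[i]), .fmt(p$r[i])))
  }
  c(lines, "end")
}

#' Write a profile to its versioned text format
#'
#' One block per position (observed frequencies + gap, target
#' probabilities, adjusted scores, effective count, deletion/insertion
#' probabilities, relative entropy), preceded by a versioned header.
#' Serialization round-trips all real-valued fields to better than 1e-6.
#'
#' @param profile A `ppa_profile`.
#' @param path Output file path.
#' @export
write_profile <- function(profile, path) {
  writeLines(profile_lines(profile), path)
  invisible(path)
}

# parse one profile starting at lines[at]; returns list(profile, next_at)
parse_profile <- function(lines, at = 1L) {
  if (at > length(lines)) stop("truncated profile: no header")
  if (lines[at] != .PROFILE_MAGIC) {
    if (grepl("^ppalign-profile", lines[at]))
      stop("profile version mismatch: ", lines[at])
    stop("not a profile record: ", lines[at])
  }
  field <- function(k, name) {
    if (k > length(lines)) stop("truncated profile: missing ", name)
    parts <- strsplit(lines[k], " ", fixed = TRUE)[[1]]
    if (parts[1] != name) stop("truncated profile: expected '", name, "' got '", parts[1], "'")
    parts[-1]
  }
  name <- paste(field(at + 1L, "name"), collapse = " ")
  m <- as.integer(field(at + 2L, "length"))
  nseq <- as.integer(field(at + 3L, "nseq"))
  tlam <- as.numeric(field(at + 4L, "table_lambda"))
  lsc <- as.numeric(field(at + 5L, "lambda_scale"))
  prov <- paste(field(at + 6L, "provenance"), collapse = " ")
  if (is.na(m) || m < 1) stop("truncated profile: bad length")
  aa <- aa_alphabet()
  f <- t_ <- s <- matrix(0, m, 20, dimnames = list(NULL, aa))
  fgap <- eff <- D <- I <- r <- numeric(m)
  oc <- integer(m)
  k <- at + 7L
  for (i in seq_len(m)) {
    ps <- field(k, "pos"); oc[i] <- as.integer(ps[2])
    fv <- as.numeric(field(k + 1L, "f"))
    f[i, ] <- fv[1:20]; fgap[i] <- fv[21]
    t_[i, ] <- as.numeric(field(k + 2L, "t"))
    s[i, ] <- as.numeric(field(k + 3L, "s"))
    qv <- as.numeric(field(k + 4L, "q"))
    eff[i] <- qv[1]; D[i] <- qv[2]; I[i] <- qv[3]; r[i] <- qv[4]
    k <- k + 5L
  }
  if (k > length(lines) || lines[k] != "end") stop("truncated profile: missing end marker")
  prof <- structure(list(name = name, m = m, nseq = nseq, orig_cols = oc,
                         f = f, f_gap = fgap, t = t_, s = s, eff = eff,
                         D = D, I = I, r = r, lambda_scale = lsc,
                         table_lambda = tlam,
                         provenance = if (prov == "NA") NA_character_ else prov),
                    class = "ppa_profile")
  list(profile = prof, next_at = k + 1L)
}

#' Read a profile from its text format
#'
#' @param path File path.
#' @return A `ppa_profile`.
#' @export
read_profile <- function(path) {
  parse_profile(readLines(path))$profile
}

#' Write a profile database
#'
#' A database is an index header (profile count, total positions, global
#' score system parameters, EVD reference) followed by the concatenated
#' profile records.
#'
#' @param profiles List of `ppa_profile` objects.
#' @param path Output path.
#' @param global A [ppa_global][build_global_score_system].
#' @param evd A [ppa_evd][fit_evd_reference].
#' @export
write_profile_db <- function(profiles, path, global, evd) {
  head <- c(.DB_MAGIC,
            paste("nprofiles", length(profiles)),
            paste("npositions", sum(vapply(profiles, `[[`, 0, "m"))),
            paste("global", .fmt(global$lambda_u), .fmt(global$K_u),
                  .fmt(global$H_u), global$n_vectors),
            paste("evd", .fmt(evd$lambda_g), .fmt(evd$mu), .fmt(evd$K_g),
                  .fmt(evd$fit_threshold), .fmt(evd$space_mn)))
  body <- unlist(lapply(profiles, profile_lines))
  writeLines(c(head, body), path)
  invisible(path)
}

#' Read a profile database
#'
#' @param path Database path.
#' @return List with `profiles`, `global`, `evd`, `n_positions`.
#' @export
read_profile_db <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != .DB_MAGIC) {
    if (length(lines) && grepl("^ppalign-profiledb", lines[1]))
      stop("database version mismatch: ", lines[1])
    stop("not a profile database")
  }
  val <- function(k, name) {
    parts <- strsplit(lines[k], " ", fixed = TRUE)[[1]]
    if (parts[1] != name) stop("truncated database: expected ", name)
    parts[-1]
  }
  np <- as.integer(val(2, "nprofiles"))
  npos <- as.integer(val(3, "npositions"))
  g <- as.numeric(val(4, "global"))
  e <- as.numeric(val(5, "evd"))
  global <- structure(list(lambda_u = g[1], K_u = g[2], H_u = g[3],
                           n_vectors = as.integer(g[4]), n_positions = npos,
                           digits = 4L), class = "ppa_global")
  evd <- structure(list(lambda_g = e[1], mu = e[2], K_g = e[3],
                        fit_threshold = e[4], stderr = c(lambda = NA, mu = NA),
                        space_mn = e[5]), class = "ppa_evd")
  profiles <- vector("list", np)
  at <- 6L
  for (i in seq_len(np)) {
    res <- parse_profile(lines, at)
    profiles[[i]] <- res$profile
    at <- res$next_at
  }
  list(profiles = profiles, global = global, evd = evd, n_positions = npos)
}
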
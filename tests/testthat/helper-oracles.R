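# Independent means-based oracle for the balanced mixed-design ANOVA:
# every SS from marginal means via explicit loops, no reuse of aov machinery.
anova_oracle <- function(cells, variable) {
  y <- cells[[variable]]
  s <- as.character(cells$subject_id); g <- as.character(cells$group)
  m <- as.character(cells$modality); i <- as.character(cells$intensity_level)
  N <- length(y); grand <- mean(y)
  mu <- function(cond) mean(y[cond])
  subjects <- sort(unique(s)); groups <- sort(unique(g))
  mods <- sort(unique(m)); ints <- sort(unique(i))
  g_of <- vapply(subjects, function(ss_) g[s == ss_][1], "")
  ss <- list(group = 0, subj_err = 0, modality = 0, `group:modality` = 0,
             mod_err = 0, intensity = 0, `group:intensity` = 0, int_err = 0,
             `modality:intensity` = 0, `group:modality:intensity` = 0,
             mi_err = 0)
  for (gg in groups) ss$group <- ss$group + sum(g == gg) * (mu(g == gg) - grand)^2
  for (sb in subjects) {
    ss$subj_err <- ss$subj_err + sum(s == sb) *
      (mu(s == sb) - mu(g == g_of[sb]))^2
  }
  for (mm in mods) ss$modality <- ss$modality + sum(m == mm) * (mu(m == mm) - grand)^2
  for (ii in ints) ss$intensity <- ss$intensity + sum(i == ii) * (mu(i == ii) - grand)^2
  for (gg in groups) for (mm in mods) {
    cond <- g == gg & m == mm
    ss$`group:modality` <- ss$`group:modality` + sum(cond) *
      (mu(cond) - mu(g == gg) - mu(m == mm) + grand)^2
  }
  for (gg in groups) for (ii in ints) {
    cond <- g == gg & i == ii
    ss$`group:intensity` <- ss$`group:intensity` + sum(cond) *
      (mu(cond) - mu(g == gg) - mu(i == ii) + grand)^2
  }
  for (mm in mods) for (ii in ints) {
    cond <- m == mm & i == ii
    ss$`modality:intensity` <- ss$`modality:intensity` + sum(cond) *
      (mu(cond) - mu(m == mm) - mu(i == ii) + grand)^2
  }
  for (gg in groups) for (mm in mods) for (ii in ints) {
    cond <- g == gg & m == mm & i == ii
    ss$`group:modality:intensity` <- ss$`group:modality:intensity` +
      sum(cond) * (mu(cond) - mu(g == gg & m == mm) - mu(g == gg & i == ii) -
                     mu(m == mm & i == ii) + mu(g == gg) + mu(m == mm) +
                     mu(i == ii) - grand)^2
  }
  for (sb in subjects) {
    gg <- g_of[sb]
    for (mm in mods) {
      ss$mod_err <- ss$mod_err + sum(s == sb & m == mm) *
        (mu(s == sb & m == mm) - mu(s == sb) -
           mu(g == gg & m == mm) + mu(g == gg))^2
    }
    for (ii in ints) {
      ss$int_err <- ss$int_err + sum(s == sb & i == ii) *
        (mu(s == sb & i == ii) - mu(s == sb) -
           mu(g == gg & i == ii) + mu(g == gg))^2
    }
    for (mm in mods) for (ii in ints) {
      gg_ <- g_of[sb]
      dev <- mu(s == sb & m == mm & i == ii) -
        mu(s == sb & m == mm) - mu(s == sb & i == ii) + mu(s == sb) -
        (mu(g == gg_ & m == mm & i == ii) - mu(g == gg_ & m == mm) -
           mu(g == gg_ & i == ii) + mu(g == gg_))
      ss$mi_err <- ss$mi_err + sum(s == sb & m == mm & i == ii) * dev^2
    }
  }
  ss$total <- sum((y - grand)^2)
  ss
}
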
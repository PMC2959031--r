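Package: errormatrix
Title: Error Matrix Overviews of Clinical Intervention Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for overviewing clinical intervention evidence with the
    four-step "error matrix": quantify random error as the standard error of
    the log effect measure (relative risk, Peto odds ratio, Mantel-Haenszel
    and Peto pooling, or back-calculation from reported confidence
    intervals), rank studies on an ordinal levels-of-evidence scale, grade
    outcomes by patient importance, classify standard errors into named
    risk bands, and assemble the step I scatter, step II grid, step III
    benefit/harm "Manhattan" figure, and step IV effect-size (number
    needed to treat) summary. Includes worked fixtures for peri-operative
    beta-blockade and antiarrhythmic maintenance of sinus rhythm, a seeded
    synthetic trial generator, ggplot2 figures, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    metafor,
    ragg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
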
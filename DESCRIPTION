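Package: subsidysim
Title: Bioeconomic Simulation of Fisheries Subsidy Reform
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-fleet global bioeconomic projection model for evaluating
    fisheries subsidy reform. Provides effort-weighted allocation of catches,
    landed value and subsidies to individual vessels, a policy engine that
    translates reform disciplines (IUU prohibitions, overfished-stock rules,
    overcapacity disciplines and cap-and-tier schemes) into fleet-level subsidy
    removals, Pella-Tomlinson surplus-production dynamics with open-access and
    managed effort adjustment, and percent-change comparisons of reform
    scenarios against a business-as-usual counterfactual. Includes a synthetic
    vessel-database generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
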
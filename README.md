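# budpredict

Beyond-use-date (BUD) prediction for compounded oral solid dosage forms.

Hospital and community pharmacies compound unlicensed oral solids — an active
pharmaceutical ingredient (API) diluted in one or two excipients, filled into
capsules and stored in glass, plastic or paper — whenever licensed products
are unavailable. Assigning a beyond-use date to such a preparation normally
requires months of stability testing. `budpredict` implements a
machine-learning alternative: a tree-ensemble regressor trained on curated
experimental stability records that predicts the BUD (in days, with a
standard error) of a formulation from the API's molecular descriptors, the
excipient composition, the API content, the packaging and the storage
temperature.

The package is aimed at formulation scientists and pharmacists who want a
reproducible, scriptable version of this pipeline: data validation, feature
encoding, model training and comparison, correlation screening, and batch
prediction over whole formulation design spaces.

## The model

Each stability record is encoded as 27 features in three blocks:

* **API descriptors (18)** — molecular weight (MW, g/mol), LogP, rotatable
  bonds (RB), polar surface area (PS, Å²), H-bond donors/acceptors
  (HBD/HBA), aromatic rings (AR); each raw value plus its class index under
  a fixed binning scheme; label codes for the API name and SMILES; and two
  composite indices

  ```
  MC  = class(MW) + class(LogP) + class(RB)           (molecule class)
  MSC = class(PS) + class(HBD) + class(HBA) + class(AR)  (molecular structure class)
  ```

* **Formulation descriptors (4)** — main-excipient code, a 7-position binary
  excipient indicator over (lactose, silica, cellulose, mannitol, sucrose,
  HPMC, reserved), API content (%) and its class.

* **Conditioning and storage descriptors (5)** — packaging code and class
  (glass = 1, plastic = 2, paper = 3), storage temperature (°C) and its
  class, and the composite

  ```
  storage class = packaging class + content class + temperature class
  ```

Binning schemes are fixed: MW 25 classes in 50 g/mol steps from below 50;
LogP 46 classes in 0.5 steps from below −10; RB/HBD/HBA/AR 8 classes in
steps of 3 from below 3; PS 21 classes in 50 Å² steps; content 10 classes in
10 % steps; temperature 15 classes in 5 °C steps. Class 1 is always the open
bottom class, interior bins are half-open `[lo, hi)`, and the top class is
open above.

The BUD regressor is an averaging ensemble of CART regression trees
(100 trees, ⌊√p⌋ features per split, bootstrap row sampling); its prediction
standard error is the per-tree standard deviation divided by √(tree count).
Six comparator families (single decision tree, random forests and tree
ensembles in classifier and regression form, gradient boosted trees in both
forms) are available for model comparison, scored with R², MAE, MSE, RMSE,
mean signed difference and MAPE on a *linear* 80/20 split (first 80 % of
rows in file order train, the rest test).

The package ships a plain-text transcription of the curated literature
dataset: 53 experimental stability records covering 22 APIs and 6
excipients (see `inst/extdata/README.md`), and a synthetic-data generator
with a known ground-truth BUD function for end-to-end validation.

## Worked example

```r
library(budpredict)

ds <- load_dataset()          # packaged curated tables
dataset_summary(ds)
#> Curated stability dataset: 53 records, 22 APIs, 6 excipients
#>   packaging (known): glass=14, plastic=13, paper=7
#>   temperature [-20, 40] degC; content [0.008, 100] %; BUD [12, 547] days

mel <- ds$apis[ds$apis$name == "Melatonin", ]
molecule_class(mel)             # 31  (MW class 5 + LogP class 24 + RB class 2)
molecular_structure_class(mel)  # 6

encode_excipients(c("lactose", "cellulose"))
#>   lactose    silica cellulose  mannitol   sucrose      hpmc  reserved
#>         1         0         1         0         0         0         0

feats <- featurize_dataset(ds)           # 27 features + bud_days
parts <- linear_partition(feats, 0.8)    # 42 train / 11 test, file order
model <- fit_bud_model(parts$train, family = "tree_ensemble_regression",
                       seed = 42)

specs <- enumerate_formulations("Melatonin", contents = 10,
                                temperatures = 25, packagings = "plastic",
                                excipient_mode = "pure")
predict_grid(model, specs, ds)[, c("excipient_1", "bud_days", "stderr_days")]
#>   excipient_1 bud_days stderr_days
#> 1     lactose    184.8       18.47
#> 2      silica    324.5       20.86
#> 3   cellulose    309.4       22.19
#> 4    mannitol    329.5       21.06
#> 5     sucrose    335.0       20.78
#> 6        hpmc    316.6       20.86
```

The grid prediction reads: melatonin at 10 % content in plastic at 25 °C is
predicted most stable in sucrose (335 ± 21 days) and least stable in lactose
(185 ± 18 days); the standard errors are ensemble dispersions, not
experimental confidence intervals.

`compare_families(ds, seed = 42)` produces the seven-family comparison
table, and `correlation_screen()` the 27-parameter Pearson screen against
any prediction set. A command-line wrapper over the same functions ships in
`inst/cli/budpredict.R`:

```sh
Rscript inst/cli/budpredict.R compare --seed 42 --out-dir run1
Rscript inst/cli/budpredict.R grid --contents 1,10,50,90 --temps 4,25,40 \
    --packagings plastic --excipient-mode both --out-dir run2
```

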
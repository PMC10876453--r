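# Default ORCHID scoring configuration.
#
# Standard portions follow ENNS/GEMRCN serving conventions (grams). Weights
# and thresholds reproduce the qualitative structure of the score — positive
# proportional rating for food groups whose consumption French dietary
# guidelines favour (all seven FPQ-based groups included), threshold rating
# with negative above-threshold weights for energy-dense groups to consume
# in moderation. The numeric weight/threshold values are an editable,
# documented approximation chosen by the package authors, not a normative
# reference: edit this file (or point load_group_config() at your own) for
# any concrete deployment.
groups:
  meat_excluding_poultry:
    label: "Meat excluding poultry"
    portion_g: 100
    source: recall
    rating: threshold
    weight: -1
    threshold: 4
  cooked_ham:
    label: "Cooked ham"
    portion_g: 50
    source: recall
    rating: positive
    weight: 1
  deli_meats_excluding_cooked_ham:
    label: "Deli meats excluding cooked ham"
    portion_g: 50
    source: recall
    rating: threshold
    weight: -2
    threshold: 2
  milk_and_fresh_dairy_products:
    label: "Milk and fresh dairy products"
    portion_g: 125
    source: recall
    rating: positive
    weight: 1
  cheese:
    label: "Cheese"
    portion_g: 30
    source: recall
    rating: positive
    weight: 1
  refined_starches_and_potatoes:
    label: "Refined starches and potatoes"
    portion_g: 150
    source: recall
    rating: positive
    weight: 1
  vegetables:
    label: "Vegetables"
    portion_g: 80
    source: recall
    rating: positive
    weight: 2
  fruits:
    label: "Fruits"
    portion_g: 80
    source: recall
    rating: positive
    weight: 2
  oils:
    label: "Oils"
    portion_g: 10
    source: recall
    rating: positive
    weight: 1
  butter_margarine_and_fresh_cream:
    label: "Butter, margarine and fresh cream"
    portion_g: 10
    source: recall
    rating: threshold
    weight: -1
    threshold: 3
  salted_aperitif_products:
    label: "Salted aperitif products"
    portion_g: 30
    source: recall
    rating: threshold
    weight: -2
    threshold: 2
  sweetened_products:
    label: "Sweetened products"
    portion_g: 30
    source: recall
    rating: threshold
    weight: -2
    threshold: 3
  sweetened_beverages:
    label: "Sweetened beverages"
    portion_g: 150
    source: recall
    rating: threshold
    weight: -3
    threshold: 1
  poultry:
    label: "Poultry"
    portion_g: 100
    source: fpq
    rating: positive
    weight: 2
  eggs:
    label: "Eggs"
    portion_g: 60
    source: fpq
    rating: positive
    weight: 2
  fatty_fish:
    label: "Fatty fish"
    portion_g: 100
    source: fpq
    rating: positive
    weight: 3
  lean_fish_and_shellfish:
    label: "Lean fish and shellfish"
    portion_g: 100
    source: fpq
    rating: positive
    weight: 2
  legumes:
    label: "Legumes"
    portion_g: 120
    source: fpq
    rating: positive
    weight: 2
  nuts:
    label: "Nuts"
    portion_g: 30
    source: fpq
    rating: positive
    weight: 2
  wholemeal_or_semi_wholemeal_products:
    label: "Wholemeal or semi-wholemeal products"
    portion_g: 100
    source: fpq
    rating: positive
    weight: 2
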
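# Gastric cancer feature dictionary: 27 risk-factor concepts, their category
# levels (ordered by increasing intensity of the factor) and the per-level
# patient counts reported for the 560-record reference cohort. Counts are the
# authoritative marginals; the baking_dish levels reported for only 421
# records gain an "other" level carrying the undocumented remainder (139).
features:
  - id: C1
    name: sex
    category: personal
    levels: [female, male]
    counts: [304, 256]
  - id: C2
    name: blood group
    category: personal
    levels: [O, B, AB, A]
    counts: [279, 78, 80, 123]
  - id: C3
    name: BMI
    category: personal
    levels: [under_18.5, 18.5_to_24.9, 25_to_29.5, over_30]
    counts: [293, 120, 76, 69]
  - id: C4
    name: age
    category: personal
    levels: [under_40, 41_to_60, over_61]
    counts: [20, 210, 330]
  - id: C5
    name: motility
    category: personal
    levels: [light, medium, high]
    counts: [156, 236, 168]
  - id: C6
    name: alcohol consumption
    category: personal
    levels: ['no', 'yes']
    counts: [475, 85]
  - id: C7
    name: exposed to chemicals
    category: personal
    levels: ['no', 'yes']
    counts: [506, 54]
  - id: C8
    name: smoking
    category: personal
    levels: ['no', 'yes']
    counts: [362, 198]
  - id: C9
    name: salt consumption
    category: diet_food
    levels: [none, low, high]
    counts: [10, 175, 375]
  - id: C10
    name: consumption of vegetable
    category: diet_food
    levels: [monthly, weekly, daily]
    counts: [320, 214, 26]
  - id: C11
    name: consumption of smoked food
    category: diet_food
    levels: [none, monthly, weekly, daily]
    counts: [5, 406, 149, 0]
  - id: C12
    name: milk consumption
    category: diet_food
    levels: ['no', 'yes']
    counts: [346, 214]
  - id: C13
    name: fast food consumption
    category: diet_food
    levels: [none, monthly, weekly]
    counts: [4, 241, 315]
  - id: C14
    name: consumption of fried foods
    category: diet_food
    levels: [none, monthly, weekly]
    counts: [0, 369, 191]
  - id: C15
    name: fruit consumption
    category: diet_food
    levels: [none, monthly, weekly]
    counts: [6, 369, 185]
  - id: C16
    name: food storage container
    category: diet_food
    levels: [style, chinese, copper, aluminum, plastic]
    counts: [9, 2, 32, 216, 301]
  - id: C17
    name: baking dish
    category: diet_food
    levels: [other, teflon, copper, aluminum]
    counts: [139, 390, 21, 10]
  - id: C18
    name: history of allergy
    category: systemic_condition
    levels: ['no', 'yes']
    counts: [471, 89]
  - id: C19
    name: family history of cancer
    category: systemic_condition
    levels: ['no', 'yes']
    counts: [349, 211]
  - id: C20
    name: family history of GC
    category: systemic_condition
    levels: ['no', 'yes']
    counts: [437, 123]
  - id: C21
    name: history of cardiovascular disease
    category: systemic_condition
    levels: ['no', 'yes']
    counts: [375, 185]
  - id: C22
    name: general status
    category: systemic_condition
    levels: [good, so_so, poor]
    counts: [79, 190, 291]
  - id: C23
    name: history of gastric reflux
    category: stomach_condition
    levels: ['no', 'yes']
    counts: [326, 234]
  - id: C24
    name: history of stomach surgery
    category: stomach_condition
    levels: ['no', 'yes']
    counts: [512, 48]
  - id: C25
    name: history of stomach infection
    category: stomach_condition
    levels: ['no', 'yes']
    counts: [384, 176]
  - id: C26
    name: mucosa status
    category: stomach_condition
    levels: [normal, swollen, red, sore]
    counts: [94, 126, 157, 183]
  - id: C27
    name: history of gastric inflammation
    category: stomach_condition
    levels: ['no', 'yes']
    counts: [397, 163]
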
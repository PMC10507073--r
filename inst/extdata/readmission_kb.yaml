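# Readmission-related knowledge base: 17 clinical concepts.
# Per concept: source table, unit, itemid used in the event tables,
# ordered states (half-open intervals, lower bound inclusive; null = open),
# gradient significance threshold (delta) and stable-trend window (hours).
chloride:
  source: lab
  unit: mEq/L
  itemid: 50902
  gradient_delta: 5
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 96}
    - {name: Normal, min: 96, max: 106}
    - {name: High, min: 106, max: null}
creatinine:
  source: lab
  unit: mg/dL
  itemid: 50912
  gradient_delta: 0.2
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 0.6}
    - {name: Normal, min: 0.6, max: 1.3}
    - {name: High, min: 1.3, max: null}
glucose:
  source: lab
  unit: mg/dL
  itemid: 50931
  gradient_delta: 10
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 70}
    - {name: Normal, min: 70, max: 100}
    - {name: High, min: 100, max: null}
hemoglobin:
  source: lab
  unit: g/dL
  itemid: 51222
  gradient_delta: 2
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 11}
    - {name: Normal, min: 11, max: 18}
    - {name: High, min: 18, max: null}
pco2:
  source: lab
  unit: mm Hg
  itemid: 50818
  gradient_delta: 2
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 38}
    - {name: Normal, min: 38, max: 42}
    - {name: High, min: 42, max: null}
ph:
  source: lab
  unit: pH
  itemid: 50820
  gradient_delta: 0.05
  stable_hours: 36
  states:
    - {name: Acidemia, min: null, max: 7.34}
    - {name: Normal, min: 7.34, max: 7.45}
    - {name: Alkalemia, min: 7.45, max: null}
phosphate:
  source: lab
  unit: mg/dL
  itemid: 50970
  gradient_delta: 0.5
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 2.4}
    - {name: Normal, min: 2.4, max: 4.1}
    - {name: High, min: 4.1, max: null}
platelets:
  source: lab
  unit: 10^9/L
  itemid: 51265
  gradient_delta: 50
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 150}
    - {name: Normal, min: 150, max: 400}
    - {name: High, min: 400, max: null}
po2:
  source: lab
  unit: torr
  itemid: 50821
  gradient_delta: 10
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 75}
    - {name: Normal, min: 75, max: 100}
    - {name: High, min: 100, max: null}
urea:
  source: lab
  unit: mg/dL
  itemid: 51006
  gradient_delta: 5
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 10}
    - {name: Normal, min: 10, max: 20}
    - {name: High, min: 20, max: null}
sodium:
  source: lab
  unit: mEq/L
  itemid: 50983
  gradient_delta: 5
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 135}
    - {name: Normal, min: 135, max: 145}
    - {name: High, min: 145, max: null}
wbc:
  source: lab
  unit: 10^9/L
  itemid: 51301
  gradient_delta: 1
  stable_hours: 36
  states:
    - {name: Low, min: null, max: 4.5}
    - {name: Normal, min: 4.5, max: 10}
    - {name: High, min: 10, max: null}
body_temperature:
  source: chart
  unit: degC
  itemid: 678
  gradient_delta: 0.5
  stable_hours: 2
  states:
    - {name: Hypothermia, min: null, max: 36.2}
    - {name: Normal, min: 36.2, max: 37.2}
    - {name: Fever, min: 37.2, max: null}
glasgow_coma_scale:
  source: chart
  unit: score
  itemid: 198
  gradient_delta: 2
  stable_hours: 2
  states:
    - {name: Severe, min: null, max: 8}
    - {name: Moderate, min: 8, max: 12}
    - {name: Mild, min: 12, max: null}
mean_pressure:
  source: chart
  unit: mm Hg
  itemid: 52
  gradient_delta: 5
  stable_hours: 1
  states:
    - {name: Low, min: null, max: 65}
    - {name: Normal, min: 65, max: 80}
    - {name: High, min: 80, max: null}
heart_rate:
  source: chart
  unit: bpm
  itemid: 211
  gradient_delta: 10
  stable_hours: 1
  states:
    - {name: Bradycardia, min: null, max: 60}
    - {name: Normal, min: 60, max: 80}
    - {name: Tachycardia, min: 80, max: null}
respiratory_rate:
  source: chart
  unit: breath/min
  itemid: 618
  gradient_delta: 3
  stable_hours: 1
  states:
    - {name: Low, min: null, max: 7}
    - {name: Normal, min: 7, max: 14}
    - {name: High, min: 14, max: null}
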
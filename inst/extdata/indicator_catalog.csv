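id,row,title,family,validity,feasibility,status,programmable
P1,1,At least one HbA1c measurement in the year,detection,8.7,7.8,accepted,TRUE
P2,2,Comprehensive foot evaluation,detection,8.7,8.2,accepted,TRUE
P3,3,Referral to the ophthalmologist,detection,8.3,7.7,accepted,TRUE
D1,4,Microalbuminuria screening (albumin/creatinine ratio),detection,8.5,5.7,discarded,FALSE
D2,5,Creatinine measurement and glomerular filtration rate,detection,8.7,5.3,discarded,FALSE
P4,6,Total-cholesterol screening in patients without prior dyslipidemia,detection,8.5,7.8,accepted,TRUE
N1,7,Smoking-cessation counseling for current smokers,non_pharmacological,8.2,8.0,accepted,FALSE
D3,8,Advice to moderate alcohol consumption,non_pharmacological,6.0,5.8,discarded,FALSE
P5,9,Nutritional counseling by the nutrition service,non_pharmacological,7.8,7.8,accepted,TRUE
N2,10,Advice on moderate aerobic exercise (150 min/week),non_pharmacological,8.2,8.0,accepted,FALSE
N3,11,Registration of adherence to dietary recommendations,non_pharmacological,8.5,7.0,accepted,FALSE
N4,12,Registration of adherence to aerobic exercise,non_pharmacological,8.5,7.0,accepted,FALSE
P6,13,Metformin for overweight/obese patients unless contraindicated,pharmacological,8.7,8.5,accepted,TRUE
D4,14,Management actions for HbA1c >= 8 or mean glucose >= 140,pharmacological,8.7,6.3,discarded,FALSE
D5,15,Registered pharmacological adherence when HbA1c >= 8,pharmacological,8.5,6.8,discarded,FALSE
P7,16,ACE inhibitor or ARB for hypertensive patients unless contraindicated,pharmacological,8.5,8.5,accepted,TRUE
P8,17,75-150 mg/day acetylsalicylic acid for patients > 40 with risk factors,pharmacological,8.5,8.2,accepted,TRUE
P9,18,Statin when total cholesterol > 200 mg/dl unless contraindicated,pharmacological,8.2,8.3,accepted,TRUE
O1,19,HbA1c < 7% or fasting glucose <= 130 mg/dl in the last 3 measurements,outcome,8.7,8.3,accepted,TRUE
O2,20,Total cholesterol < 200 mg/dl in the last measurement,outcome,8.7,8.2,accepted,TRUE
O3,21,Blood pressure < 130/80 mmHg in the last 3 measurements,outcome,8.7,8.5,accepted,TRUE
O4,22,Overweight/obese patients who lost >= 5% body weight in the year,outcome,8.0,7.7,accepted,TRUE
O5,23,Composite: glycemic and blood-pressure control plus cholesterol < 200,outcome,8.5,7.5,accepted,TRUE
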
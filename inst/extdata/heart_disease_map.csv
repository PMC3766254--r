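concept,Exercise,Food Habits,Cholesterol,Body Weight,Blood Pressure,Heart Disease
Exercise,1,0,-1,-1,0,-1
Food Habits,0,1,1,1,1,0
Cholesterol,0,0,1,0,0,1
Body Weight,0,0,0,1,1,1
Blood Pressure,0,0,1,0,1,1
Heart Disease,0,0,0,0,0,0
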
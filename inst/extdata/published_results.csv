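partition,group,n,total_cost_nonsurgical,total_cost_usual,delta_cost,total_qalys_nonsurgical,total_qalys_usual,delta_qalys,per_person_cost_nonsurgical,per_person_cost_usual,per_person_delta_cost,per_person_qalys_nonsurgical,per_person_qalys_usual,per_person_delta_qalys,inmb
base,base,61394,1092713293,1582021235,-489307942,624489,650902,-26412,17798,25768,-7970,10.17,10.60,-0.43,-4090
state,no_mild,12473,215267310,317132491,-101865181,128513,132142,-3629,17259,25426,-8167,10.30,10.59,-0.29,11
state,moderate,30706,546735808,790850027,-244114220,316909,330169,-13260,17805,25755,-7950,10.32,10.75,-0.43,-4156
state,severe_extreme,18215,330710175,474038717,-143328542,179067,188591,-9523,18156,26025,-7869,9.83,10.35,-0.52,-6788
age_band,45-54,3943,91483696,121227208,-29743512,51226,54724,-3498,23202,30745,-7543,12.99,13.88,-0.89,-17326
age_band,55-64,16567,326072933,447603176,-121530243,200279,207567,-7288,19682,27018,-7336,12.09,12.53,-0.44,-4996
age_band,65-74,26240,457322473,660314256,-202991783,268203,278403,-10200,17428,25164,-7736,10.22,10.61,-0.39,-3161
age_band,75-84,14644,217834191,352876596,-135042405,104781,110208,-5427,14875,24097,-9222,7.16,7.53,-0.37,-1166
sex,female,33069,606179084,850139140,-243960056,342503,358205,-15702,18331,25708,-7377,10.36,10.83,-0.47,-5934
sex,male,28325,486534209,731882095,-245347886,281987,292696,-10710,17177,25839,-8662,9.96,10.33,-0.38,-1938
hospital,public,16514,271856461,390514531,-118658069,166920,174342,-7422,16462,23647,-7185,10.11,10.56,-0.45,-5414
hospital,private,44878,820594644,1191065311,-370470667,459045,477586,-18541,18285,26540,-8255,10.23,10.64,-0.41,-3327
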
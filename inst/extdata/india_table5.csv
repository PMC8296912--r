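outcome,covariate,elasticity,ci_k,contribution,pct
immunisation,household_wealth,0.0439,0.2870,0.0504,30.7361
immunisation,residence,0.0061,-0.0697,-0.0017,-1.0411
immunisation,mother_education,0.0462,0.2405,0.0444,27.0784
immunisation,husband_education,-0.0041,0.1688,-0.0028,-1.6769
immunisation,mother_age,0.0923,-0.0043,-0.0016,-0.9585
immunisation,head_sex,0.0097,-0.0087,-0.0003,-0.2046
immunisation,media_exposure,-0.0021,0.4366,-0.0037,-2.2752
immunisation,antenatal_care,0.0353,0.1957,0.0276,16.8309
immunisation,postnatal_care,0.0223,0.0536,0.0048,2.9094
immunisation,delivery_place,0.0787,0.0762,0.0240,14.6296
immunisation,birth_order,-0.0226,-0.1719,0.0155,9.4771
food_security,malnutrition,-0.0093,-0.1470,0.0055,-9.9556
food_security,household_wealth,-0.0069,0.2870,-0.0079,14.4277
food_security,residence,0.0314,-0.0697,-0.0088,15.9989
food_security,mother_education,-0.0616,0.2405,-0.0593,108.2039
food_security,husband_education,0.0172,0.1688,0.0116,-21.2282
food_security,mother_age,-0.0559,-0.0043,0.0010,-1.7370
food_security,head_sex,-0.0513,-0.0398,0.0082,-14.8992
food_security,child_sex,0.0205,-0.0087,-0.0007,1.2982
food_security,household_size,0.0001,-0.0098,-0.0000,0.0085
nutrition,food_insecurity,-0.0252,-0.0172,0.0017,-0.7480
nutrition,household_wealth,-0.1391,0.2870,-0.1597,69.0023
nutrition,residence,-0.0230,-0.0697,0.0064,-2.7763
nutrition,mother_education,-0.0591,0.2405,-0.0568,24.5562
nutrition,husband_education,-0.0186,0.1688,-0.0126,5.4366
nutrition,mother_age,-0.0299,-0.0043,0.0005,-0.2202
nutrition,head_sex,0.1050,-0.0398,-0.0167,7.2264
nutrition,child_sex,-0.0099,-0.0087,0.0003,-0.1478
nutrition,household_size,-0.0058,-0.0098,0.0002,-0.0972
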
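vessel_type,community,potter_id,metric,mean,cv_pct,n_trials
money_bank,prajapati,GA,height_cm,16.3,5.4,5
money_bank,prajapati,KA,height_cm,18.4,2.3,5
money_bank,prajapati,BA,height_cm,14.5,5.9,5
money_bank,prajapati,AR,height_cm,15.2,2.0,5
money_bank,multani_kumhar,KD,height_cm,15.9,2.7,5
money_bank,multani_kumhar,NA,height_cm,12.9,4.8,5
money_bank,multani_kumhar,YA,height_cm,17.7,3.1,5
money_bank,prajapati,GA,max_diameter_cm,14.3,4.2,5
money_bank,prajapati,KA,max_diameter_cm,13.9,2.4,5
money_bank,prajapati,BA,max_diameter_cm,12.3,8.7,5
money_bank,prajapati,AR,max_diameter_cm,12.8,4.5,5
money_bank,multani_kumhar,KD,max_diameter_cm,14.2,3.4,5
money_bank,multani_kumhar,NA,max_diameter_cm,11.1,1.3,5
money_bank,multani_kumhar,YA,max_diameter_cm,17.4,2.1,5
money_bank,prajapati,GA,esa_cm2,543.3,8.3,5
money_bank,prajapati,KA,esa_cm2,596.9,4.6,5
money_bank,prajapati,BA,esa_cm2,422.8,13.2,5
money_bank,prajapati,AR,esa_cm2,466.9,8.5,5
money_bank,multani_kumhar,KD,esa_cm2,500.6,5.5,5
money_bank,multani_kumhar,NA,esa_cm2,330.9,6.2,5
money_bank,multani_kumhar,YA,esa_cm2,745.8,4.1,5
handiya,prajapati,GA,height_cm,13.9,7.0,5
handiya,prajapati,KA,height_cm,13.8,2.0,5
handiya,prajapati,BA,height_cm,12.7,2.7,5
handiya,prajapati,AR,height_cm,13.2,2.5,4
handiya,prajapati,GA,max_diameter_cm,15.3,8.3,5
handiya,prajapati,KA,max_diameter_cm,16.6,1.1,5
handiya,prajapati,BA,max_diameter_cm,14.9,3.9,5
handiya,prajapati,AR,max_diameter_cm,14.8,1.9,4
handiya,prajapati,GA,esa_cm2,587.0,14.7,5
handiya,prajapati,KA,esa_cm2,640.0,3.2,5
handiya,prajapati,BA,esa_cm2,525.4,7.4,5
handiya,prajapati,AR,esa_cm2,557.0,5.1,4
kullar,prajapati,GA,height_cm,14.7,5.2,5
kullar,prajapati,KA,height_cm,12.5,3.5,5
kullar,prajapati,BA,height_cm,14.4,3.4,5
kullar,prajapati,AR,height_cm,14.2,2.7,5
kullar,prajapati,GA,max_diameter_cm,12.0,3.6,5
kullar,prajapati,KA,max_diameter_cm,11.4,2.0,5
kullar,prajapati,BA,max_diameter_cm,12.7,3.5,5
kullar,prajapati,AR,max_diameter_cm,12.1,5.2,5
kullar,prajapati,GA,esa_cm2,513.8,7.8,5
kullar,prajapati,KA,esa_cm2,413.3,5.9,5
kullar,prajapati,BA,esa_cm2,528.8,7.8,5
kullar,prajapati,AR,esa_cm2,473.1,8.1,5
handi,multani_kumhar,KD,height_cm,12.1,3.7,5
handi,multani_kumhar,NA,height_cm,12.7,2.3,5
handi,multani_kumhar,YA,height_cm,14.3,4.0,5
handi,multani_kumhar,KD,max_diameter_cm,17.4,1.5,5
handi,multani_kumhar,NA,max_diameter_cm,17.8,1.2,5
handi,multani_kumhar,YA,max_diameter_cm,20.5,1.9,5
handi,multani_kumhar,KD,esa_cm2,580.0,3.6,5
handi,multani_kumhar,NA,esa_cm2,640.5,2.7,5
handi,multani_kumhar,YA,esa_cm2,842.5,5.5,5
kulfi,multani_kumhar,KD,height_cm,9.2,3.4,5
kulfi,multani_kumhar,NA,height_cm,8.33,4.1,5
kulfi,multani_kumhar,YA,height_cm,9.7,3.6,5
kulfi,multani_kumhar,KD,max_diameter_cm,12.5,2.3,5
kulfi,multani_kumhar,NA,max_diameter_cm,12.3,3.6,5
kulfi,multani_kumhar,YA,max_diameter_cm,14.3,2.0,5
kulfi,multani_kumhar,KD,esa_cm2,346.3,3.5,5
kulfi,multani_kumhar,NA,esa_cm2,320.6,6.7,5
kulfi,multani_kumhar,YA,esa_cm2,445.1,4.4,5
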
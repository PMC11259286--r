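"statement_id","text"
1,"Hard to get [medication assisted] treatment when basic needs are not being met"
2,"Not having access to technology to connect to programs"
3,"Not having access to shelter/housing"
4,"Not having access to food"
5,"Being able to sign up for opioid use disorder treatment on the spot"
6,"Makes a big difference when it seems like my doctor really cares"
7,"Not having a phone makes it hard to stay connected to providers and fill prescriptions"
8,"Mandatory drug testing leads to decreased retention in opioid use disorder treatment programs"
9,"Mandatory drug testing in opioid use disorder treatment programs is stigmatizing"
10,"Mandatory drug testing promotes a return to dangerous fentanyl laced street drugs"
11,"Reduced ratio of medication-assisted treatment (MAT) providers to those seeking treatment"
12,"Buprenorphine is not hard to get"
13,"You only do the treatment if you want to"
14,"You will quit if you want to quit"
15,"You do not need the medicine to quit"
16,"The medicine is legal but otherwise medicine and drugs are the same"
17,"Methadone and buprenorphine make you nod just like drugs, so they are the same"
18,"You can get high off the prescription for free so people do that and also buy drugs and get high off that"
19,"Forced because it is either jail or the treatment program so that is not really a choice"
20,"There are drugs at the treatment program"
21,"Easy to get medication-assisted treatment (MAT)"
22,"No one really wants treatment"
23,"They do not really care at the treatment program, they are not trying to help for real"
24,"Services are not available at all times"
25,"There are legal barriers that fell during covid that have made it easier to get treatment"
26,"Allowing for larger take homes makes it easier"
27,"Urine tests"
28,"Drugs are easier to get than Suboxone"
29,"Drugs do not have urine tests or waiting times"
30,"Treatment programs do not have enough hours on the weekends or nights"
31,"Everyone has a moment where treatment is in the front of your mind and if you miss that moment, addicts are really good at making excuses not to make it today"
32,"Monday to Friday, holidays off is not really how this works- need medication-assisted treatment (MAT) available all the time"
33,"Not enough promotion of Suboxone"
34,"Not enough awareness of Suboxone"
35,"Need more billboard campaigns or flyers of Suboxone"
36,"Limited technology literacy. Hard to use tablet/phone when you are used to a desktop"
37,"You do not want to stop consuming the opioids"
38,"Once you are complying with treatment, it creates dependency, which causes addiction to said medication"
39,"Naltrexone requires full detoxification so initiating treatment among active users becomes difficult"
40,"Medications are not combined with behavioral counseling"
41,"Medication-assisted treatment is expensive"
42,"Once people are doing bad they get depressed and they feel like they can just do whatever"
43,"I am trying to start over, to get away from it before anything gets worse, like I could get HIV from some of these other guys"
44,"I have other medical issues that are more important"
45,"Case manager does not help"
46,"Medication assisted treatment does not offer vouchers for food or other things I need, I am always spending $10 to stay on someone's couch"
47,"Feel like I have no foundation (to even think about starting treatment)"
48,"People just don't want to go through the sickness (so they are not willing to go through that to start buprenorphine)"
49,"Suboxone being sold on the street"
50,"People have bad mental health, they do not tackle that first"
51,"People feel like it is too late for them, if they cannot get a home or if they got back from jail, just go back to the same place"
52,"Cannot get people to do treatment before they are ready"
53,"People start young, becomes a way of life"
54,"It is difficult to start because you have to let yourself be in withdrawal for almost 3 days before you can take it unless you want to put yourself in the incident withdrawals which is hell on earth"
55,"The social stigma of using buprenorphine/Suboxone"
56,"The inability to work certain jobs due to medication in system"
57,"The temptation to revert back to other opiate drugs like oxycodone and heroin"
58,"The fear of becoming physically and psychologically dependent on another substance"
59,"The long use of drugs like heroin makes it difficult to start the medication for opioid use disorder"
60,"Some people are afraid of the medication side effects"
61,"Majority of the people who have started using medication-assisted treatment (MAT) might fail to continue on the way due to stress"
62,"Lack of encouragement"
63,"Lack of awareness of medication-assisted treatment (MAT)"
64,"Poverty. Many people who have opioid use disorder are not able to afford medication-assisted treatment"
65,"People in remote places are unable to access medication-assisted treatment (MAT)"
66,"I think because it is sometimes difficult to stick with and keep up as it is used multiple times a day"
67,"Buprenorphine/Suboxone does not completely help you either. It is a very hit or miss type of drug that can either really help you or be your downfall"
68,"Opioids relaxes a lot, takes the pain away"
69,"Suboxone is expensive and addictive"
70,"Medication-assisted treatment is difficult to keep taking because it just makes your body feel terrible, it makes me feel like I want to be dead"
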